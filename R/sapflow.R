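# Heat-ratio sap flow: heat pulse velocity, sap flux density, transpiration
# and sap-flow-derived canopy conductance, plus reference-period
# normalization.
#
# Gauge constants are not hard-coded: the heat-ratio method gives
# vh = (k/x) * ln(ratio), and the vh -> vs -> Js chain is a pair of
# configurable linear factors (identity by default). All headline outputs
# are normalized to a reference period, so absolute gauge constants cancel.

#' Gauge calibration for the heat-ratio conversion chain
#'
#' @param thermal_diffusivity_k thermal diffusivity of fresh sapwood,
#'   cm^2 s^-1 (default 0.0025, a standard green-wood value).
#' @param probe_spacing_x distance between heater and sensor, cm
#'   (default 0.5).
#' @param vh_to_vs_factor multiplicative heat-pulse-to-sap-velocity factor
#'   (default 1; absorbs wound and wood-fraction corrections).
#' @param vs_to_js_factor sap velocity to sap flux density factor,
#'   g cm^-3 (default 1).
#' @return object of class `gauge_calibration`.
#' @export
gauge_calibration <- function(thermal_diffusivity_k = 0.0025,
                              probe_spacing_x = 0.5,
                              vh_to_vs_factor = 1,
                              vs_to_js_factor = 1) {
  vals <- c(thermal_diffusivity_k, probe_spacing_x, vh_to_vs_factor,
            vs_to_js_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_domain("all gauge calibration factors must be positive and finite")
  structure(list(thermal_diffusivity_k = thermal_diffusivity_k,
                 probe_spacing_x = probe_spacing_x,
                 vh_to_vs_factor = vh_to_vs_factor,
                 vs_to_js_factor = vs_to_js_factor),
            class = "gauge_calibration")
}

#' Heat pulse velocity from a heat ratio
#'
#' \eqn{v_h = (k/x)\,\ln(\mathrm{ratio})} in cm s^-1. A ratio of 1 means no
#' flow; ratios below 1 give negative (reverse) velocities.
#'
#' @param heat_ratio downstream/upstream temperature-rise ratio (> 0).
#' @param cal a [gauge_calibration()] object.
#' @return heat pulse velocity, cm s^-1.
#' @export
heat_pulse_velocity <- function(heat_ratio, cal = gauge_calibration()) {
  check_number(heat_ratio, "heat_ratio")
  if (any(heat_ratio <= 0))
    stop_domain("heat_ratio must be positive")
  (cal$thermal_diffusivity_k / cal$probe_spacing_x) * log(heat_ratio)
}

#' Sap flux density and daily totals from heat pulse velocity
#'
#' \eqn{J_s = v_h \cdot f_{vs} \cdot f_{Js}} per record; daily totals
#' integrate \eqn{J_s \Delta t} over each calendar day (rectangle rule on
#' the regular half-hourly grid).
#'
#' @param series data frame with `timestamp` (POSIXct) and `vh` (cm s^-1).
#' @param cal a [gauge_calibration()] object.
#' @param interval_s record spacing, seconds (default 1800).
#' @param max_missing_frac days missing more than this fraction of expected
#'   intervals get `NA` totals (default 0.1).
#' @return list with `series` (input plus `js`, g cm^-2 s^-1) and `daily`
#'   (data frame `date`, `total_js` in g cm^-2 day^-1, `n_records`).
#' @export
sap_flux_density <- function(series, cal = gauge_calibration(),
                             interval_s = 1800, max_missing_frac = 0.1) {
  if (is.null(cal)) stop_domain("a gauge_calibration is required")
  check_increasing_time(series$timestamp)
  series$js <- series$vh * cal$vh_to_vs_factor * cal$vs_to_js_factor
  day <- as.Date(series$timestamp, tz = "UTC")
  expected <- 86400 / interval_s
  daily <- do.call(rbind, lapply(split(seq_along(day), day), function(i) {
    data.frame(date = day[i[1]],
               total_js = if (length(i) >= (1 - max_missing_frac) * expected)
                 sum(series$js[i]) * interval_s else NA_real_,
               n_records = length(i))
  }))
  rownames(daily) <- NULL
  list(series = series, daily = daily)
}

#' Fit the midday sap-velocity to transpiration map of one individual
#'
#' Least-squares linear regression of cuvette transpiration E
#' (mmol m^-2 s^-1) on midday heat pulse velocity, used to scale continuous
#' sap-flow records into leaf-area-specific transpiration.
#'
#' @param vh midday heat pulse velocities, cm s^-1.
#' @param E paired transpiration measurements, mmol m^-2 s^-1.
#' @param individual_id label carried into the result.
#' @return object of class `vh_to_E_map` with `slope`, `intercept`,
#'   `r_squared`, `n`, `individual_id`.
#' @export
fit_vh_to_E <- function(vh, E, individual_id = NA_character_) {
  if (length(vh) != length(E)) stop_domain("vh and E must pair up")
  if (length(vh) < 3) stop_domain("need at least 3 midday (vh, E) pairs")
  if (stats::sd(vh) == 0) stop_domain("degenerate fit: vh is constant")
  fit <- stats::lm(E ~ vh)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((E - mean(E))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = length(vh), individual_id = individual_id),
            class = "vh_to_E_map")
}

#' Sap-flow-derived transpiration
#'
#' Applies an individual's fitted vh-to-E map to a vh series; negative
#' predictions are floored at zero (no negative transpiration).
#'
#' @param vh heat pulse velocity series, cm s^-1.
#' @param map a [fit_vh_to_E()] result.
#' @param individual_id if supplied, must match the map's individual.
#' @return transpiration E_sf, mmol m^-2 s^-1.
#' @export
transpiration_from_sapflow <- function(vh, map, individual_id = NULL) {
  stopifnot(inherits(map, "vh_to_E_map"))
  if (!is.null(individual_id) && !is.na(map$individual_id) &&
      individual_id != map$individual_id)
    stop_domain("vh-to-E map was fitted for individual '%s', not '%s'",
                map$individual_id, individual_id)
  pmax(map$slope * vh + map$intercept, 0)
}

#' Physical constants for the conductance conversion
#'
#' @param rho_w density of water, kg m^-3 (default 1000).
#' @param G_v gas constant for water vapour, m^3 kPa kg^-1 K^-1
#'   (default 0.462).
#' @param p_atm barometric pressure, kPa (default 101.325); used only by the
#'   barometric alpha mode.
#' @return object of class `physical_constants`.
#' @export
physical_constants <- function(rho_w = 1000, G_v = 0.462, p_atm = 101.325) {
  structure(list(rho_w = rho_w, G_v = G_v, p_atm = p_atm),
            class = "physical_constants")
}

#' Sap-flow-derived stomatal conductance
#'
#' \eqn{G_{sf} = \alpha\, E_{sf} / VPD}. In the default (verbatim) mode
#' \eqn{\alpha = \rho_w G_v T_K}; `alpha_mode = "barometric"` uses
#' \eqn{\alpha = P_{atm}} instead. Because all seasonal results are
#' expressed as percent of a reference period, \eqn{\alpha} cancels and the
#' choice does not affect normalized output. Records at or below the VPD
#' floor are masked (`NA`) rather than divided.
#'
#' @param esf transpiration, mmol m^-2 s^-1.
#' @param vpd vapour pressure deficit, kPa.
#' @param t_air air temperature, degC.
#' @param constants a [physical_constants()] object.
#' @param vpd_floor kPa; records with `vpd <= vpd_floor` return `NA`
#'   (default 0.1).
#' @param alpha_mode `"verbatim"` (rho_w * G_v * T_K) or `"barometric"`
#'   (P_atm).
#' @return conductance G_sf, same flux units as `esf` per kPa ratio;
#'   attribute `masked` gives the indices excluded by the VPD floor.
#' @export
gsf <- function(esf, vpd, t_air, constants = physical_constants(),
                vpd_floor = 0.1, alpha_mode = c("verbatim", "barometric")) {
  alpha_mode <- match.arg(alpha_mode)
  n <- max(length(esf), length(vpd), length(t_air))
  esf <- rep_len(esf, n); vpd <- rep_len(vpd, n); t_air <- rep_len(t_air, n)
  alpha <- switch(alpha_mode,
                  verbatim = constants$rho_w * constants$G_v * (t_air + 273.15),
                  barometric = rep_len(constants$p_atm, n))
  out <- rep(NA_real_, n)
  ok <- vpd > vpd_floor
  out[ok] <- alpha[ok] * esf[ok] / vpd[ok]
  attr(out, "masked") <- which(!ok)
  out
}

#' Normalize a daily series to a reference window
#'
#' Expresses each value as a percentage of the reference statistic (mean by
#' default, maximum by option) computed over a mesic early-season window in
#' which gas exchange is at or near its unstressed maximum.
#'
#' @param daily data frame with `date` and a value column.
#' @param value_col name of the value column.
#' @param reference_window `Date` vector of length 2 (start, end inclusive).
#' @param statistic `"mean"` (default) or `"max"`.
#' @param min_days minimum valid reference days (default 5).
#' @return the input with an added `<value_col>_pct` column; attribute
#'   `reference_value` records the denominator.
#' @export
normalize_to_reference <- function(daily, value_col, reference_window,
                                   statistic = c("mean", "max"),
                                   min_days = 5) {
  statistic <- match.arg(statistic)
  if (length(reference_window) != 2)
    stop_domain("reference_window must be (start, end)")
  v <- daily[[value_col]]
  in_win <- daily$date >= reference_window[1] & daily$date <= reference_window[2]
  ref_vals <- v[in_win & !is.na(v)]
  if (length(ref_vals) < min_days)
    stop_domain("reference window holds %d valid days; need >= %d",
                length(ref_vals), min_days)
  ref <- if (statistic == "mean") mean(ref_vals) else max(ref_vals)
  if (ref <= 0) stop_domain("reference statistic must be positive")
  daily[[paste0(value_col, "_pct")]] <- 100 * v / ref
  attr(daily, "reference_value") <- ref
  daily
}
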