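# Micrometeorology: vapour pressure, dew point, dew events, soil-probe
# calibration, daily summaries.
#
# Thermodynamic conversions use the Magnus form with the constants of
# Lawrence (2005): A = 17.625 (dimensionless), B = 243.04 degC, and a
# leading coefficient of 0.61094 kPa for saturation vapour pressure.

#' Magnus constants for dew-point and vapour-pressure calculations
#'
#' @param A dimensionless Magnus coefficient (default 17.625).
#' @param B Magnus temperature constant in degC (default 243.04).
#' @param es0 saturation vapour pressure at 0 degC in kPa (default 0.61094).
#' @return an object of class `magnus_constants`.
#' @export
magnus_constants <- function(A = 17.625, B = 243.04, es0 = 0.61094) {
  check_number(A, "A"); check_number(B, "B"); check_number(es0, "es0")
  structure(list(A = A, B = B, es0 = es0), class = "magnus_constants")
}

#' Saturation vapour pressure of air (Magnus form)
#'
#' \eqn{e_s(T) = e_{s0} \exp(A T / (B + T))} in kPa. Strictly increasing in
#' temperature; the domain requires \eqn{T > -B}.
#'
#' @param t_air air temperature, degC.
#' @param constants a [magnus_constants()] object.
#' @return saturation vapour pressure, kPa.
#' @export
saturation_vapour_pressure <- function(t_air, constants = magnus_constants()) {
  check_number(t_air, "t_air")
  if (any(t_air <= -constants$B))
    stop_domain("t_air must exceed -B = %g degC", -constants$B)
  constants$es0 * exp(constants$A * t_air / (constants$B + t_air))
}

#' Vapour pressure deficit
#'
#' \eqn{VPD = e_s(T)(1 - RH/100)} in kPa; zero exactly at saturation.
#'
#' @param t_air air temperature, degC.
#' @param rh relative humidity, percent in \[0, 100\].
#' @param constants a [magnus_constants()] object.
#' @return VPD, kPa (non-negative).
#' @export
vpd <- function(t_air, rh, constants = magnus_constants()) {
  check_number(rh, "rh")
  if (any(rh < 0 | rh > 100)) stop_domain("rh must lie in [0, 100]")
  saturation_vapour_pressure(t_air, constants) * (1 - rh / 100)
}

#' Dew-point temperature
#'
#' The Magnus dew-point inversion
#' \deqn{T_{dew} = B\,[\ln(RH/100) + A T/(B+T)] / [A - \ln(RH/100) - A T/(B+T)]}
#' with A = 17.625 and B = 243.04 degC. Always at or below the air
#' temperature, with equality exactly at RH = 100.
#'
#' @param t_air air temperature, degC.
#' @param rh relative humidity, percent in (0, 100].
#' @param constants a [magnus_constants()] object.
#' @return dew-point temperature, degC.
#' @export
dew_point <- function(t_air, rh, constants = magnus_constants()) {
  check_number(t_air, "t_air"); check_number(rh, "rh")
  if (any(rh <= 0 | rh > 100)) stop_domain("rh must lie in (0, 100]")
  A <- constants$A; B <- constants$B
  g <- log(rh / 100) + A * t_air / (B + t_air)
  B * g / (A - g)
}

#' Detect dew events in a half-hourly meteorological series
#'
#' A record is dew-flagged iff it is rain-free, the leaf-wetness sensor
#' resistance is below `resistance_threshold`, and the air temperature is
#' within `temp_window` of the dew point. Consecutive flagged records merge
#' into one event spanning their half-hour intervals.
#'
#' @param series data frame with columns `timestamp` (POSIXct), `t_air`,
#'   `rh`, `rain`, `wetness_resistance`.
#' @param resistance_threshold kOhm; default 400.
#' @param temp_window degC; default 0.5.
#' @param interval_s record spacing in seconds (default 1800); used to close
#'   the final interval of an event.
#' @param constants a [magnus_constants()] object.
#' @return data frame with columns `start`, `end` (POSIXct) and `duration`
#'   (hours); zero rows when nothing is flagged.
#' @export
detect_dew_events <- function(series, resistance_threshold = 400,
                              temp_window = 0.5, interval_s = 1800,
                              constants = magnus_constants()) {
  if (nrow(series) == 0)
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration = numeric()))
  check_increasing_time(series$timestamp)
  flag <- dew_flags(series, resistance_threshold, temp_window, constants)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration = numeric()))
  start <- series$timestamp[starts[keep]]
  end <- series$timestamp[ends[keep]] + interval_s
  data.frame(start = start, end = end,
             duration = as.numeric(difftime(end, start, units = "hours")))
}

# Per-record dew rule; also used by the synthetic generator's self-check.
dew_flags <- function(series, resistance_threshold = 400, temp_window = 0.5,
                      constants = magnus_constants()) {
  rh <- pmin(pmax(series$rh, 1e-6), 100)
  td <- dew_point(series$t_air, rh, constants)
  series$rain == 0 &
    series$wetness_resistance < resistance_threshold &
    abs(series$t_air - td) <= temp_window
}

#' Calibrate a soil-moisture probe against gravimetric samples
#'
#' Ordinary least-squares regression of gravimetric water content (g/g) on
#' raw probe output. At least three pairs with a non-constant predictor are
#' required.
#'
#' @param probe_raw raw probe readings.
#' @param gravimetric gravimetric soil water content, g water per g dry soil.
#' @return an object of class `soil_calibration` with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
calibrate_soil_probe <- function(probe_raw, gravimetric) {
  if (length(probe_raw) != length(gravimetric))
    stop_domain("probe and gravimetric vectors must have equal length")
  if (length(probe_raw) < 3)
    stop_domain("need at least 3 calibration pairs, got %d", length(probe_raw))
  if (stats::sd(probe_raw) == 0)
    stop_domain("degenerate fit: probe readings are constant")
  fit <- stats::lm(gravimetric ~ probe_raw)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((gravimetric - mean(gravimetric))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = length(probe_raw)),
            class = "soil_calibration")
}

#' Apply a soil calibration to raw probe readings
#'
#' @param calibration a [calibrate_soil_probe()] result.
#' @param probe_raw raw probe readings.
#' @return calibrated soil water content, g/g.
#' @export
apply_soil_calibration <- function(calibration, probe_raw) {
  stopifnot(inherits(calibration, "soil_calibration"))
  calibration$intercept + calibration$slope * probe_raw
}

#' @export
print.soil_calibration <- function(x, ...) {
  cat(sprintf("Soil probe calibration: slope = %.3f, intercept = %.3f, R2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Daily summaries of a half-hourly meteorological series
#'
#' One row per calendar day: mean midday (12:00-14:00) VPD, total rainfall,
#' mean soil moisture, and a completeness flag. Days with no midday records
#' carry `NA` midday VPD; days with fewer than `min_frac` of the expected
#' half-hours are flagged incomplete.
#'
#' @param series data frame with `timestamp`, `t_air`, `rh`, `rain` and
#'   optionally `soil_moisture`.
#' @param min_frac minimum fraction of the 48 expected intervals for a day
#'   to count as complete (default 0.8).
#' @return data frame with columns `date`, `midday_vpd`, `rain_total`,
#'   `soil_moisture`, `n_records`, `complete`.
#' @export
daily_summaries <- function(series, min_frac = 0.8) {
  check_increasing_time(series$timestamp)
  day <- as.Date(series$timestamp, tz = "UTC")
  hr <- as.POSIXlt(series$timestamp, tz = "UTC")$hour +
    as.POSIXlt(series$timestamp, tz = "UTC")$min / 60
  v <- vpd(series$t_air, series$rh)
  midday <- hr >= 12 & hr < 14
  days <- sort(unique(day))
  out <- lapply(days, function(d) {
    i <- day == d
    im <- i & midday
    data.frame(
      date = d,
      midday_vpd = if (any(im)) mean(v[im]) else NA_real_,
      rain_total = sum(series$rain[i]),
      soil_moisture = if (!is.null(series$soil_moisture))
        mean(series$soil_moisture[i]) else NA_real_,
      n_records = sum(i),
      complete = sum(i) >= min_frac * 48
    )
  })
  do.call(rbind, out)
}
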