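# Synthetic fixtures: pulsed-rainfall weather with dew nights, bucket-model
# soil moisture, species-archetype plant responses (sap flow, water
# potentials, stomatal conductance), and drying optical image stacks.
#
# Every generator is a pure function of (config, seed): the seed is part of
# the config object, set once per call, and recorded in the output
# attributes. Defaults encode the stated study conditions: a 182-day
# (Oct-Mar) summer, 90 mm of dry-season vs 253 mm of normal-season rain,
# three > 20 mm events only in the normal season, frequent dew nights, and
# Mediterranean-shrubland diel cycles.

#' Weather generator configuration
#'
#' @param season_length_days length of the summer season (default 182,
#'   October through March).
#' @param summer_rain_total target seasonal rainfall, mm.
#' @param n_large_events number of large (> 20 mm) rain events.
#' @param small_event_rate small (< 10 mm) events per week.
#' @param diel_T_range peak-to-trough diel temperature amplitude, degC.
#' @param diel_RH_range diel relative-humidity amplitude, percent.
#' @param dew_probability_per_night probability a night carries dew.
#' @param t_mean seasonal mean air temperature, degC.
#' @param rh_mean seasonal mean relative humidity, percent.
#' @param start_date first day of the series.
#' @param seed integer RNG seed.
#' @return object of class `weather_config`.
#' @export
weather_config <- function(season_length_days = 182,
                           summer_rain_total = 90,
                           n_large_events = 1,
                           small_event_rate = 1,
                           diel_T_range = 12,
                           diel_RH_range = 40,
                           dew_probability_per_night = 0.5,
                           t_mean = 20, rh_mean = 65,
                           start_date = as.Date("2012-10-01"),
                           seed = 1L) {
  if (season_length_days <= 0)
    stop_domain("season_length_days must be positive")
  if (summer_rain_total < 0) stop_domain("summer_rain_total must be >= 0")
  if (dew_probability_per_night < 0 || dew_probability_per_night > 1)
    stop_domain("dew_probability_per_night must lie in [0, 1]")
  if (20 * n_large_events > summer_rain_total && summer_rain_total > 0)
    stop_domain("%d large (> 20 mm) events cannot fit in %g mm total",
                n_large_events, summer_rain_total)
  structure(list(season_length_days = as.integer(season_length_days),
                 summer_rain_total = summer_rain_total,
                 n_large_events = as.integer(n_large_events),
                 small_event_rate = small_event_rate,
                 diel_T_range = diel_T_range, diel_RH_range = diel_RH_range,
                 dew_probability_per_night = dew_probability_per_night,
                 t_mean = t_mean, rh_mean = rh_mean,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "weather_config")
}

#' Preset weather configurations for the two study seasons
#'
#' The dry season carries 90 mm of summer rain with one moderate event; the
#' normal season carries 253 mm with three large (> 20 mm) events and a
#' higher small-event rate.
#'
#' @param seed integer RNG seed.
#' @return a [weather_config()].
#' @export
weather_config_dry <- function(seed = 1L) {
  weather_config(summer_rain_total = 90, n_large_events = 1,
                 small_event_rate = 1,
                 start_date = as.Date("2012-10-01"), seed = seed)
}

#' @rdname weather_config_dry
#' @export
weather_config_normal <- function(seed = 1L) {
  weather_config(summer_rain_total = 253, n_large_events = 3,
                 small_event_rate = 1.5,
                 start_date = as.Date("2013-10-01"), seed = seed)
}

#' Bucket model for soil-moisture dynamics
#'
#' A single-store bucket: rain above `infiltration_threshold_mm` (daily
#' total) infiltrates at `infiltration_fraction` percent volumetric per mm;
#' storage decays exponentially toward `residual` at
#' `drainage_rate + evapotranspiration_coupling` per day and is capped at
#' `capacity`.
#'
#' @param capacity field capacity, percent volumetric.
#' @param residual residual moisture, percent volumetric.
#' @param infiltration_fraction moisture gain per mm of infiltrating rain,
#'   percent per mm.
#' @param drainage_rate drainage decay rate, per day.
#' @param evapotranspiration_coupling additional decay from plant water
#'   uptake, per day.
#' @param infiltration_threshold_mm daily rain totals at or below this do
#'   not reach the layer (default 0; use ~10 for deep layers that small
#'   events never wet).
#' @return object of class `bucket_model`.
#' @export
bucket_model <- function(capacity = 12, residual = 2,
                         infiltration_fraction = 0.15,
                         drainage_rate = 0.03,
                         evapotranspiration_coupling = 0.02,
                         infiltration_threshold_mm = 0) {
  if (residual >= capacity)
    stop_domain("residual (%g) must be below capacity (%g)", residual, capacity)
  if (infiltration_fraction < 0 || drainage_rate < 0 ||
      evapotranspiration_coupling < 0)
    stop_domain("bucket rates must be non-negative")
  structure(list(capacity = capacity, residual = residual,
                 infiltration_fraction = infiltration_fraction,
                 drainage_rate = drainage_rate,
                 evapotranspiration_coupling = evapotranspiration_coupling,
                 infiltration_threshold_mm = infiltration_threshold_mm),
            class = "bucket_model")
}

# deep (50-70 cm probe layer) and shallow (root-zone) presets
bucket_deep <- function() bucket_model(infiltration_threshold_mm = 10)
bucket_shallow <- function() bucket_model(capacity = 10, residual = 0.5,
                                          infiltration_fraction = 0.4,
                                          drainage_rate = 0.12,
                                          evapotranspiration_coupling = 0.08)

#' Soil moisture from rainfall through a bucket model
#'
#' @param rain rainfall per interval, mm.
#' @param bucket a [bucket_model()].
#' @param timestamps optional POSIXct vector paired with `rain`; required
#'   when the bucket has a daily infiltration threshold.
#' @param initial initial storage (default capacity).
#' @param interval_s interval length, seconds (default 1800).
#' @return soil moisture series, percent volumetric, bounded in
#'   \[residual, capacity\]; bucket carried in attribute `bucket`.
#' @export
generate_soil_moisture <- function(rain, bucket = bucket_model(),
                                   timestamps = NULL, initial = NULL,
                                   interval_s = 1800) {
  stopifnot(inherits(bucket, "bucket_model"))
  if (any(rain < 0)) stop_domain("rain must be non-negative")
  eff_rain <- rain
  if (bucket$infiltration_threshold_mm > 0) {
    if (is.null(timestamps))
      stop_domain("timestamps required for a daily infiltration threshold")
    day <- as.Date(timestamps, tz = "UTC")
    daily <- tapply(rain, day, sum)
    blocked <- names(daily)[daily <= bucket$infiltration_threshold_mm]
    eff_rain[as.character(day) %in% blocked] <- 0
  }
  k <- (bucket$drainage_rate + bucket$evapotranspiration_coupling) *
    interval_s / 86400
  decay <- exp(-k)
  s <- numeric(length(rain))
  cur <- initial %||% bucket$capacity
  for (i in seq_along(rain)) {
    cur <- min(bucket$capacity,
               cur + bucket$infiltration_fraction * eff_rain[i])
    cur <- bucket$residual + (cur - bucket$residual) * decay
    s[i] <- cur
  }
  attr(s, "bucket") <- bucket
  s
}

#' Generate a half-hourly synthetic weather season
#'
#' Produces diel temperature/humidity cycles with day-to-day noise, pulsed
#' rainfall (large events at fixed season fractions, small events as a
#' daily Bernoulli process, afternoon-weighted within the day), dew nights
#' on which 01:00-05:00 records are brought to saturation with a wet leaf
#' sensor, and a deep-layer soil-moisture/probe trace driven by the rain.
#' The rainfall column sums to `summer_rain_total` exactly.
#'
#' @param config a [weather_config()].
#' @param soil_calibration_line `c(slope, intercept)` of the probe
#'   calibration used to back-transform soil moisture into raw probe units
#'   (default the study line `c(1.53, -1.54)` in g/g).
#' @return data frame of half-hourly records: `timestamp`, `t_air`, `rh`,
#'   `rain`, `wetness_resistance`, `soil_probe_raw`, `soil_moisture`,
#'   `soil_depth`, `dew_night`; attributes `config` and `seed`.
#' @export
generate_weather <- function(config = weather_config(),
                             soil_calibration_line = c(1.53, -1.54)) {
  stopifnot(inherits(config, "weather_config"))
  set.seed(config$seed)
  nd <- config$season_length_days
  n <- nd * 48L
  ts <- as.POSIXct(config$start_date, tz = "UTC") + 1800 * (seq_len(n) - 1L)
  hour <- rep(seq(0, 23.5, by = 0.5), nd)
  dayi <- rep(seq_len(nd), each = 48L)

  # temperature: AR(1) day-to-day anomaly + mid-season bump + diel cycle
  anom <- stats::filter(stats::rnorm(nd, 0, 1.5), 0.7, "recursive")
  season <- 3 * sin(pi * (seq_len(nd) - 1) / (nd - 1))
  t_day <- config$t_mean + season + as.numeric(anom)
  t_air <- t_day[dayi] +
    (config$diel_T_range / 2) * cos(2 * pi * (hour - 14) / 24)

  rh <- config$rh_mean -
    (config$diel_RH_range / 2) * cos(2 * pi * (hour - 14) / 24) +
    stats::rnorm(n, 0, 3)
  rh <- pmin(pmax(rh, 5), 100)

  # rainfall: large events at fixed season fractions, small events thinned
  # Bernoulli per day; amounts rescaled so the season sums exactly
  rain_day <- numeric(nd)
  if (config$summer_rain_total > 0) {
    large_amt <- numeric(0)
    if (config$n_large_events > 0) {
      fr <- seq(0.25, 0.75, length.out = config$n_large_events)
      large_days <- pmax(1L, round(fr * nd))
      large_amt <- 20 + stats::runif(config$n_large_events, 2, 10)
    }
    p_small <- min(1, config$small_event_rate / 7)
    small_days <- which(stats::runif(nd) < p_small)
    if (config$n_large_events > 0)
      small_days <- setdiff(small_days, large_days)
    remainder <- config$summer_rain_total - sum(large_amt)
    if (length(small_days) > 0 && remainder > 0) {
      w <- stats::runif(length(small_days), 0.5, 1)
      small_amt <- remainder * w / sum(w)
      rain_day[small_days] <- small_amt
    } else if (config$n_large_events > 0) {
      large_amt <- large_amt * config$summer_rain_total / sum(large_amt)
    }
    if (config$n_large_events > 0) rain_day[large_days] <- large_amt
    # absorb any residual into the wettest day so the total is exact
    gap <- config$summer_rain_total - sum(rain_day)
    rain_day[which.max(rain_day)] <- rain_day[which.max(rain_day)] + gap
  }
  rain <- numeric(n)
  for (d in which(rain_day > 0)) {
    # spread the day's rain over afternoon half-hours (14:00-16:30)
    slots <- (d - 1L) * 48L + 29:33
    w <- stats::runif(5, 0.5, 1)
    rain[slots] <- rain_day[d] * w / sum(w)
  }

  # dew nights: saturate 01:00-05:00, wet leaf sensor; no rain then by
  # construction (rain falls in the afternoon)
  dew_night_day <- stats::runif(nd) < config$dew_probability_per_night
  dew_idx <- which(dew_night_day[dayi] & hour >= 1 & hour < 5)
  rh[dew_idx] <- 100
  wet <- stats::runif(n, 800, 3000)
  wet[dew_idx] <- stats::runif(length(dew_idx), 100, 300)

  soil <- generate_soil_moisture(rain, bucket_deep(), timestamps = ts)
  grav <- soil / 100  # volumetric % ~ g/g for this soil
  probe_raw <- (grav - soil_calibration_line[2]) / soil_calibration_line[1]

  out <- data.frame(timestamp = ts, t_air = t_air, rh = rh, rain = rain,
                    wetness_resistance = wet, soil_probe_raw = probe_raw,
                    soil_moisture = as.numeric(soil), soil_depth = 50,
                    dew_night = dew_night_day[dayi])
  attr(out, "config") <- config
  attr(out, "seed") <- config$seed
  attr(out, "bucket") <- attr(soil, "bucket")
  out
}

#' Species archetype: simulation parameters of one growth form
#'
#' Encodes how a growth form couples to shallow vs deep soil water, vapour
#' pressure deficit and dew, and its hydraulic limits (minimum dry-season
#' water potential and sigmoid vulnerability parameters).
#'
#' @param name label: `"ericoid"`, `"proteoid"`, `"restioid"` or custom.
#' @param rooting_depth_weighting weight on the shallow soil layer in
#'   \[0, 1\] (1 = fully shallow rooted).
#' @param vpd_sensitivity dimensionless scaling of the midday drawdown and
#'   stomatal VPD response.
#' @param soil_sensitivity exponent of the soil-limitation factor
#'   (relative moisture ^ soil_sensitivity); larger = more drought
#'   sensitive.
#' @param dew_use_fraction fraction of a dew night's credit the species can
#'   use (0 = none).
#' @param max_vh maximum heat pulse velocity, cm s^-1.
#' @param psi_min_dry asymptotic minimum predawn water potential under
#'   full soil depletion, MPa (< 0).
#' @param vulnerability_a sigmoid slope a, MPa^-1 (< 0).
#' @param vulnerability_b P50, MPa (< 0).
#' @return object of class `species_archetype`.
#' @export
species_archetype <- function(name, rooting_depth_weighting, vpd_sensitivity,
                              soil_sensitivity, dew_use_fraction, max_vh,
                              psi_min_dry, vulnerability_a, vulnerability_b) {
  if (vulnerability_a >= 0) stop_domain("vulnerability_a must be negative")
  if (psi_min_dry >= 0) stop_domain("psi_min_dry must be negative")
  if (max_vh < 0) stop_domain("max_vh must be non-negative")
  if (rooting_depth_weighting < 0 || rooting_depth_weighting > 1)
    stop_domain("rooting_depth_weighting must lie in [0, 1]")
  structure(list(name = name,
                 rooting_depth_weighting = rooting_depth_weighting,
                 vpd_sensitivity = vpd_sensitivity,
                 soil_sensitivity = soil_sensitivity,
                 dew_use_fraction = dew_use_fraction,
                 max_vh = max_vh, psi_min_dry = psi_min_dry,
                 vulnerability_a = vulnerability_a,
                 vulnerability_b = vulnerability_b),
            class = "species_archetype")
}

#' Preset archetypes for the three fynbos growth forms
#'
#' Hydraulic limits follow the study species: the ericoid shrub is shallow
#' rooted, drought exposed (psi_min near -4 MPa) but embolism resistant
#' (P50 -5.68 MPa, slope solved from its printed dry-season loss); the
#' proteoid overstorey shrub is deep rooted with stable water status
#' (P50 -3.50 MPa); the restioid is shallow rooted, dew-using, with a
#' vulnerable culm xylem (P50 -2.30 MPa, steep slope solved from its
#' printed dry-season loss).
#'
#' @return a [species_archetype()].
#' @export
archetype_ericoid <- function() {
  species_archetype("ericoid", rooting_depth_weighting = 1,
                    vpd_sensitivity = 1.2, soil_sensitivity = 2,
                    dew_use_fraction = 0, max_vh = 0.002,
                    psi_min_dry = -4.0,
                    vulnerability_a = solve_sigmoid_slope(-4.0, 7.3, -5.68),
                    vulnerability_b = -5.68)
}

#' @rdname archetype_ericoid
#' @export
archetype_proteoid <- function() {
  species_archetype("proteoid", rooting_depth_weighting = 0.1,
                    vpd_sensitivity = 0.8, soil_sensitivity = 0.8,
                    dew_use_fraction = 0, max_vh = 0.004,
                    psi_min_dry = -1.5,
                    vulnerability_a = -4, vulnerability_b = -3.50)
}

#' @rdname archetype_ericoid
#' @export
archetype_restioid <- function() {
  species_archetype("restioid", rooting_depth_weighting = 0.9,
                    vpd_sensitivity = 0.6, soil_sensitivity = 0.6,
                    dew_use_fraction = 0.3, max_vh = 0.0015,
                    psi_min_dry = -1.9,
                    vulnerability_a = solve_sigmoid_slope(-1.9, 1.8, -2.30),
                    vulnerability_b = -2.30)
}

# saturating map from relative soil moisture to predawn water potential
psi_predawn_map <- function(rel, psi_min_dry, psi_wet = -0.2, c_half = 3) {
  depletion <- (1 - rel) / (1 - rel + c_half * rel)
  psi_wet - (psi_wet - psi_min_dry) * depletion
}

#' Generate sap-flow, water-potential and stomatal-conductance responses
#'
#' Drives a species archetype with a weather series and a deep-layer soil
#' series. A fast shallow root-zone bucket is filled from the same rain;
#' root-weighted relative moisture (plus a dew credit on mornings after dew
#' nights, scaled by `dew_use_fraction`) sets predawn water potential
#' through a saturating map; midday water potential is predawn minus a
#' VPD-scaled transpirational drawdown; half-hourly heat pulse velocity is
#' `max_vh` times light, soil-limitation and VPD factors.
#'
#' @param archetype a [species_archetype()].
#' @param weather a [generate_weather()] data frame.
#' @param soil deep-layer soil moisture series aligned with `weather`
#'   (default the weather's own `soil_moisture` column).
#' @param campaign_every_days spacing of water-potential campaigns, days
#'   (default 14).
#' @param n_individuals individuals sampled per campaign (default 5).
#' @param obs_noise_sd_mpa between-individual water-potential noise, MPa
#'   (default 0.05).
#' @param dew_credit relative-moisture credit of one dew night before
#'   `dew_use_fraction` scaling (default 0.15).
#' @param gs_max maximum leaf stomatal conductance, mol m^-2 s^-1
#'   (default 0.25).
#' @param seed RNG seed for observation noise (default 1).
#' @return list with `vh` (data frame `timestamp`, `vh`), `psi`
#'   (campaign-level observations: `date`, `individual_id`, `species`,
#'   `period`, `psi`), `gs` (daily midday `date`, `gs`), and `daily_truth`
#'   (the generating predawn/midday map per day).
#' @export
generate_plant_series <- function(archetype, weather, soil = NULL,
                                  campaign_every_days = 14,
                                  n_individuals = 5,
                                  obs_noise_sd_mpa = 0.05,
                                  dew_credit = 0.15, gs_max = 0.25,
                                  seed = 1L) {
  stopifnot(inherits(archetype, "species_archetype"))
  soil <- soil %||% weather$soil_moisture
  if (length(soil) != nrow(weather))
    stop_domain("weather and soil series are not aligned (%d vs %d records)",
                nrow(weather), length(soil))
  set.seed(seed)
  ts <- weather$timestamp
  day <- as.Date(ts, tz = "UTC")
  days <- sort(unique(day))
  hour <- as.POSIXlt(ts, tz = "UTC")$hour + as.POSIXlt(ts, tz = "UTC")$min / 60

  deep_bucket <- attr(soil, "bucket") %||% attr(weather, "bucket") %||%
    bucket_deep()
  shallow <- generate_soil_moisture(weather$rain, bucket_shallow(),
                                    timestamps = ts)
  sb <- attr(shallow, "bucket")
  rel_shallow <- pmin(pmax((as.numeric(shallow) - sb$residual) /
                             (sb$capacity - sb$residual), 0), 1)
  rel_deep <- pmin(pmax((as.numeric(soil) - deep_bucket$residual) /
                          (deep_bucket$capacity - deep_bucket$residual), 0), 1)
  w <- archetype$rooting_depth_weighting
  rel <- w * rel_shallow + (1 - w) * rel_deep

  # dew credit: mornings after a dew night relax the effective depletion
  dew_gain <- if (!is.null(weather$dew_night))
    archetype$dew_use_fraction * dew_credit * as.numeric(weather$dew_night)
  else 0
  rel_eff <- pmin(rel + dew_gain, 1)

  vpd_series <- vpd(weather$t_air, weather$rh)
  light <- pmax(0, sin(pi * (hour - 6) / 12))
  f_soil <- rel_eff^archetype$soil_sensitivity
  f_vpd <- vpd_series / (vpd_series + 1)
  vh <- archetype$max_vh * light * f_soil * f_vpd

  # daily truth: predawn at 04:00, midday drawdown from mean 12:00-14:00 VPD
  predawn_idx <- match(paste(days, 4), paste(day, hour))
  rel_pd <- rel_eff[predawn_idx]
  psi_pd <- psi_predawn_map(rel_pd, archetype$psi_min_dry)
  midday <- hour >= 12 & hour < 14
  vpd_md <- vapply(days, function(d)
    mean(vpd_series[day == d & midday]), 0)
  openness <- vapply(days, function(d) {
    i <- day == d & midday
    mean(f_soil[i] * 1 / (1 + archetype$vpd_sensitivity * vpd_series[i]))
  }, 0)
  drawdown <- 0.6 * archetype$vpd_sensitivity * vpd_md / (vpd_md + 1) *
    (0.2 + 0.8 * openness)
  psi_md <- psi_pd - drawdown
  gs_md <- gs_max * openness

  # campaign observations: n individuals, noise never violates pd >= md
  camp_days <- days[seq(1, length(days), by = campaign_every_days)]
  obs <- do.call(rbind, lapply(camp_days, function(d) {
    i <- match(d, days)
    pd <- pmin(psi_pd[i] + stats::rnorm(n_individuals, 0, obs_noise_sd_mpa), 0)
    md <- pd - drawdown[i] * (1 + abs(stats::rnorm(n_individuals, 0, 0.1)))
    data.frame(date = d,
               individual_id = paste0(archetype$name, "_", seq_len(n_individuals)),
               species = archetype$name,
               period = rep(c("predawn", "midday"), each = n_individuals),
               psi = c(pd, md))
  }))
  list(vh = data.frame(timestamp = ts, vh = vh),
       psi = obs,
       gs = data.frame(date = days, gs = gs_md),
       daily_truth = data.frame(date = days, psi_predawn = psi_pd,
                                psi_midday = psi_md, vpd_midday = vpd_md,
                                rel_moisture = rel_pd))
}

#' Simulate one soil-probe calibration dataset
#'
#' Draws probe readings uniformly over `probe_range`, maps them through the
#' calibration line `gravimetric = slope * probe + intercept`, and adds
#' Gaussian noise with standard deviation `noise_frac` of the gravimetric
#' range. Used to benchmark slope recovery of [calibrate_soil_probe()].
#'
#' @param n_pairs number of (probe, gravimetric) pairs (default 20).
#' @param slope,intercept generating line (defaults 1.53, -1.54, the study
#'   calibration in g/g per probe unit).
#' @param noise_frac noise sd as a fraction of the gravimetric range
#'   (default 0.05).
#' @param probe_range range of raw probe readings (default c(1.05, 1.2),
#'   spanning gravimetric contents of roughly 0.07-0.3 g/g).
#' @param seed integer RNG seed.
#' @return data frame with `probe_raw` and `gravimetric`.
#' @export
simulate_soil_calibration <- function(n_pairs = 20, slope = 1.53,
                                      intercept = -1.54, noise_frac = 0.05,
                                      probe_range = c(1.05, 1.2), seed = 1L) {
  set.seed(seed)
  probe <- stats::runif(n_pairs, probe_range[1], probe_range[2])
  grav <- slope * probe + intercept
  noise_sd <- noise_frac * diff(range(grav))
  data.frame(probe_raw = probe,
             gravimetric = grav + stats::rnorm(n_pairs, 0, noise_sd))
}

#' Synthetic optical-stack configuration
#'
#' @param image_shape `c(rows, cols)` in pixels (default 60 x 60).
#' @param n_vessels number of vessels (>= 1); each occupies a 3 x 4 pixel
#'   block on a 6-pixel grid, so `prod(floor(image_shape/6))` must be at
#'   least `n_vessels`.
#' @param a,b sigmoid vulnerability parameters from which each vessel's
#'   embolism water potential is drawn (`a` < 0 MPa^-1, `b` = P50 MPa).
#' @param drying_schedule optional data frame `timestamp`, `psi` (monotone
#'   non-increasing); the default ramps linearly from -0.1 MPa to below the
#'   most resistant drawn vessel over `n_frames` 5-minute scans.
#' @param n_frames frames in the default schedule (default 144, a 12-hour
#'   dry-down).
#' @param noise_sd grey-level noise standard deviation (default 0).
#' @param seed integer RNG seed.
#' @return object of class `stack_config`.
#' @export
stack_config <- function(image_shape = c(60, 60), n_vessels = 100,
                         a = -2, b = -3, drying_schedule = NULL,
                         n_frames = 144, noise_sd = 0, seed = 1L) {
  if (n_vessels < 1) stop_domain("n_vessels must be >= 1")
  if (a >= 0) stop_domain("a must be negative")
  if (prod(floor(image_shape / 6)) < n_vessels)
    stop_domain("image_shape %dx%d holds at most %d vessels",
                image_shape[1], image_shape[2], prod(floor(image_shape / 6)))
  if (!is.null(drying_schedule) && any(diff(drying_schedule$psi) > 0))
    stop_domain("drying_schedule must be non-increasing")
  structure(list(image_shape = image_shape, n_vessels = as.integer(n_vessels),
                 a = a, b = b, drying_schedule = drying_schedule,
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "stack_config")
}

#' Generate a drying optical image stack with known embolism truth
#'
#' Places `n_vessels` 12-pixel vessels on a grid; draws each vessel's
#' embolism water potential by inverse-CDF sampling so that the true
#' cumulative embolism fraction follows the sigmoid vulnerability model
#' with (`a`, `b`); brightens a vessel's pixels once and permanently at the
#' first frame whose schedule water potential drops below its threshold;
#' optionally adds Gaussian grey-level noise.
#'
#' @param config a [stack_config()].
#' @return list with `stack` (an [image_stack()]), `timeline` (data frame
#'   `timestamp`, `psi`), `vessel_psi` (true thresholds), `vessel_pixels`
#'   (list of pixel indices) and `config`.
#' @export
generate_optical_stack <- function(config = stack_config()) {
  stopifnot(inherits(config, "stack_config"))
  set.seed(config$seed)
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  # inverse-CDF draw: F(psi) = 1/(1 + exp(a (psi - b))) is the fraction of
  # vessels NOT yet embolized... solved for psi at uniform quantile u
  u <- pmin(pmax(stats::runif(config$n_vessels), 0.001), 0.999)
  vessel_psi <- config$b + log((1 - u) / u) / config$a

  sched <- config$drying_schedule
  if (is.null(sched)) {
    psi <- seq(-0.1, min(vessel_psi) - 0.3, length.out = config$n_frames)
    sched <- data.frame(
      timestamp = as.POSIXct("2020-12-01 08:00:00", tz = "UTC") +
        300 * (seq_len(config$n_frames) - 1L),
      psi = psi)
  }
  n_frames <- nrow(sched)

  # vessel placement on a 6-px grid; each vessel is a 3x4 block
  cells_r <- floor(nr / 6); cells_c <- floor(nc / 6)
  cell <- sample.int(cells_r * cells_c, config$n_vessels)
  cr <- (cell - 1L) %% cells_r; cc <- (cell - 1L) %/% cells_r
  vessel_pixels <- lapply(seq_len(config$n_vessels), function(v) {
    rows <- cr[v] * 6L + 2:4
    cols <- cc[v] * 6L + 2:5
    as.integer(outer(rows, (cols - 1L) * nr, `+`))
  })

  # frame index at which each vessel embolizes (first psi below threshold)
  flip_frame <- vapply(vessel_psi, function(p) {
    i <- which(sched$psi < p)
    if (length(i)) i[1] else NA_integer_
  }, 0L)

  frames <- vector("list", n_frames)
  base <- matrix(100, nr, nc)
  for (f in seq_len(n_frames)) {
    m <- base
    on <- which(!is.na(flip_frame) & flip_frame <= f)
    if (length(on)) m[unlist(vessel_pixels[on])] <- 180
    if (config$noise_sd > 0)
      m <- m + stats::rnorm(nr * nc, 0, config$noise_sd)
    frames[[f]] <- round(pmin(pmax(m, 0), 255))
  }
  list(stack = image_stack(frames, sched$timestamp, sample_id = "synthetic"),
       timeline = sched, vessel_psi = vessel_psi,
       vessel_pixels = vessel_pixels, config = config)
}
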