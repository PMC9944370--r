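# Generators: weather, bucket soil moisture, plant responses, image stacks.

test_that("weather generator hits the rain budget and is reproducible", {
  w <- generate_weather(weather_config(summer_rain_total = 90, seed = 1))
  expect_equal(sum(w$rain), 90, tolerance = 0.01 * 90 / 90)
  expect_true(all(w$rain >= 0))
  expect_true(all(vpd(w$t_air, w$rh) >= 0))

  w0 <- generate_weather(weather_config(summer_rain_total = 0,
                                        n_large_events = 0, seed = 1))
  expect_true(all(w0$rain == 0))

  # bit-identical on identical config + seed
  a <- generate_weather(weather_config_normal(seed = 7))
  b <- generate_weather(weather_config_normal(seed = 7))
  expect_identical(a, b)
  expect_false(identical(a$rain,
                         generate_weather(weather_config_normal(seed = 8))$rain))

  expect_error(weather_config(season_length_days = 0), "positive")
  expect_error(weather_config(summer_rain_total = -1), "0")
  expect_error(weather_config(dew_probability_per_night = 1.5), "\\[0, 1\\]")
  expect_error(weather_config(summer_rain_total = 30, n_large_events = 2),
               "large")
})

test_that("the normal season carries three large events, the dry season none", {
  wn <- generate_weather(weather_config_normal(seed = 3))
  daily <- tapply(wn$rain, as.Date(wn$timestamp, tz = "UTC"), sum)
  expect_equal(sum(daily > 20), 3)
  expect_equal(sum(wn$rain), 253)
  wd <- generate_weather(weather_config_dry(seed = 3))
  expect_equal(sum(wd$rain), 90)
  expect_lte(sum(tapply(wd$rain, as.Date(wd$timestamp, tz = "UTC"), sum) > 20), 1)
})

test_that("dew-labelled nights satisfy the detector's rule", {
  w <- generate_weather(weather_config(dew_probability_per_night = 0.6,
                                       seed = 21))
  lt <- as.POSIXlt(w$timestamp, tz = "UTC")
  labelled <- w$dew_night & (lt$hour + lt$min / 60) >= 1 &
    (lt$hour + lt$min / 60) < 5
  flag <- w$rain == 0 & w$wetness_resistance < 400 &
    abs(w$t_air - dew_point(w$t_air, pmax(w$rh, 1e-6))) <= 0.5
  # generator and detector agree on at least 95% of labelled frames
  expect_gte(mean(flag[labelled]), 0.95)
  # and the detector never fires off dew windows
  expect_equal(sum(flag[!labelled]), 0)
})

test_that("bucket soil moisture decays exponentially and respects bounds", {
  bk <- bucket_model(capacity = 12, residual = 2, drainage_rate = 0.03,
                     evapotranspiration_coupling = 0.02)
  n <- 48 * 20
  s <- generate_soil_moisture(rep(0, n), bk)
  # closed form of the zero-rain bucket: exponential decay toward residual
  k <- (0.03 + 0.02) / 48
  expected <- 2 + (12 - 2) * exp(-k * seq_len(n))
  expect_equal(as.numeric(s), expected, tolerance = 1e-12)
  expect_true(all(s >= 2 & s <= 12))
  expect_true(all(diff(s) <= 0))

  # single pulse: step up then monotone decay; matches hand recursion
  rain <- rep(0, 200); rain[100] <- 10
  sp <- generate_soil_moisture(rain, bk, initial = 5)
  cur <- 5; oracle <- numeric(200)
  for (i in 1:200) {
    cur <- min(12, cur + 0.15 * rain[i])
    cur <- 2 + (cur - 2) * exp(-k)
    oracle[i] <- cur
  }
  expect_equal(as.numeric(sp), oracle, tolerance = 1e-12)
  expect_gt(sp[100], sp[99])
  expect_true(all(diff(sp[100:200]) < 0))

  expect_error(bucket_model(capacity = 5, residual = 5), "below capacity")
  expect_error(generate_soil_moisture(c(-1, 0), bk), "non-negative")

  # degenerate capacity ~ residual: constant at the floor
  bk2 <- bucket_model(capacity = 2 + 1e-9, residual = 2)
  s2 <- generate_soil_moisture(rep(0, 10), bk2, initial = 2)
  expect_equal(as.numeric(s2), rep(2, 10), tolerance = 1e-8)
})

test_that("daily infiltration threshold blocks small events only", {
  ts <- half_hours(48 * 4)
  rain <- rep(0, length(ts))
  rain[30] <- 5          # small event, day 1
  rain[48 * 2 + 30] <- 25  # large event, day 3
  deep <- generate_soil_moisture(rain, bucket_model(infiltration_threshold_mm = 10),
                                 timestamps = ts, initial = 5)
  expect_lt(deep[31], deep[29])          # small pulse ignored
  expect_gt(deep[48 * 2 + 31], deep[48 * 2 + 29])  # large pulse infiltrates
})

test_that("plant series: water-potential ordering and archetype responses", {
  w <- generate_weather(weather_config_dry(seed = 42))
  er <- generate_plant_series(archetype_ericoid(), w, seed = 5)

  # predawn >= midday for every individual and date
  wide <- merge(er$psi[er$psi$period == "predawn", c("date", "individual_id", "psi")],
                er$psi[er$psi$period == "midday", c("date", "individual_id", "psi")],
                by = c("date", "individual_id"))
  expect_true(all(wide$psi.x >= wide$psi.y))

  # dry season drives the ericoid to its archetype minimum
  expect_lt(abs(min(er$daily_truth$psi_predawn) - archetype_ericoid()$psi_min_dry),
            0.2)

  # sap flow tracks soil moisture
  expect_gt(cor(er$daily_truth$rel_moisture,
                tapply(er$vh$vh, as.Date(er$vh$timestamp, tz = "UTC"), sum)),
            0.5)

  # zero max_vh silences the gauge
  ar0 <- species_archetype("null", 1, 1, 1, 0, 0, -1, -2, -3)
  expect_true(all(generate_plant_series(ar0, w, seed = 1)$vh$vh == 0))

  # archetype ordering of minimum midday psi under the dry default
  pr <- generate_plant_series(archetype_proteoid(), w, seed = 5)
  re <- generate_plant_series(archetype_restioid(), w, seed = 5)
  expect_lt(min(er$daily_truth$psi_midday), min(re$daily_truth$psi_midday))
  expect_lt(min(er$daily_truth$psi_midday), min(pr$daily_truth$psi_midday))

  expect_error(generate_plant_series(archetype_ericoid(), w, soil = 1:10),
               "aligned")
  expect_error(species_archetype("bad", 1, 1, 1, 0, 1, -1,
                                 vulnerability_a = 2, vulnerability_b = -3),
               "negative")
})

test_that("small rain pulses move shallow-rooted sap flow, not deep-rooted", {
  # controlled scenario: 70 rainless days, one 5 mm pulse, 20 more dry days
  cfg <- weather_config(season_length_days = 90, summer_rain_total = 0,
                        n_large_events = 0, dew_probability_per_night = 0,
                        seed = 13)
  w <- generate_weather(cfg)
  pulse_slot <- 48 * 69 + 30
  w$rain[pulse_slot] <- 5
  w$soil_moisture <- as.numeric(
    generate_soil_moisture(w$rain, bucket_model(infiltration_threshold_mm = 10),
                           timestamps = w$timestamp))

  daily_vh <- function(p) tapply(p$vh$vh, as.Date(p$vh$timestamp, tz = "UTC"), sum)

  # fully shallow, no dew use: >= 5-fold rise over the pre-pulse dry spell
  shallow <- species_archetype("shallow", rooting_depth_weighting = 1,
                               vpd_sensitivity = 1.2, soil_sensitivity = 2,
                               dew_use_fraction = 0, max_vh = 0.002,
                               psi_min_dry = -4, vulnerability_a = -2,
                               vulnerability_b = -5)
  dv <- daily_vh(generate_plant_series(shallow, w, seed = 2))
  before <- mean(dv[66:69]); after <- max(dv[71:74])
  expect_gte(after / before, 5)

  # deep-rooted proteoid: the same pulse moves daily sap flow < 1.4-fold
  dvp <- daily_vh(generate_plant_series(archetype_proteoid(), w, seed = 2))
  expect_lt(max(dvp[71:74]) / mean(dvp[66:69]), 1.4)
})

test_that("optical stacks embolize each vessel once, at its drawn threshold", {
  cfg <- stack_config(n_vessels = 40, a = -2, b = -3, seed = 9)
  out <- generate_optical_stack(cfg)
  expect_identical(out$stack$frames,
                   generate_optical_stack(cfg)$stack$frames)

  # every vessel's pixels flip exactly once, at the first frame whose
  # schedule psi is below the drawn threshold
  for (v in seq_len(40)) {
    px <- out$vessel_pixels[[v]][1]
    trace <- vapply(out$stack$frames, function(m) m[px], 0)
    flips <- which(diff(trace) != 0)
    expect_length(flips, 1)
    expect_equal(flips + 1L, which(out$timeline$psi < out$vessel_psi[v])[1])
  }

  # final frame: all vessel pixels embolized
  final <- out$stack$frames[[length(out$stack$frames)]]
  expect_true(all(final[unlist(out$vessel_pixels)] == 180))

  # true cumulative curve follows the sigmoid within binomial sampling error
  psi_grid <- seq(-1, -5, by = -0.25)
  emp <- vapply(psi_grid, function(p) mean(out$vessel_psi >= p), 0)
  theor <- (100 - 100 / (1 + exp(-2 * (psi_grid - -3)))) / 100
  expect_lt(max(abs(emp - theor)), 3 * sqrt(0.25 / 40))

  # single vessel: cumulative curve is one step 0 -> 100
  one <- generate_optical_stack(stack_config(n_vessels = 1, seed = 2))
  ev <- detect_embolism_events(difference_images(one$stack))
  expect_equal(sum(ev$n_pixels > 0), 1)
  expect_equal(cumulative_embolism(ev)$percent[ev$n_pixels > 0], 100)

  expect_error(stack_config(n_vessels = 0), "1")
  expect_error(stack_config(n_vessels = 500), "at most")
  bad_sched <- data.frame(timestamp = half_hours(3), psi = c(-1, -2, -1.5))
  expect_error(stack_config(drying_schedule = bad_sched), "non-increasing")
})
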