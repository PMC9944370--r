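# End-to-end orchestration: a reproducible synthetic demo run through
# weather -> micromet -> sap flow -> vulnerability -> seasonal analysis,
# with per-stage CSV outputs and a JSON run manifest.

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param seed global seed; every stochastic stage receives a seed derived
#'   from it, recorded in the manifest.
#' @param seasons named list of [weather_config()] objects (default the dry
#'   and normal presets).
#' @param archetypes list of [species_archetype()] objects (default the
#'   three growth-form presets).
#' @param stages character vector of stages to run, in dependency order
#'   among `"simulate"`, `"micromet"`, `"sapflow"`, `"vcurve"`,
#'   `"analyze"`.
#' @param reference_days length of the early-season reference window, days
#'   (default 21).
#' @param psi_tolerance rehydration tolerance, MPa (default 0.1).
#' @param n_vessels vessels per simulated vulnerability stack (default 100).
#' @param vpd_floor kPa floor for conductance records (default 0.1).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("fynhyd_run_"), seed = 1L,
                       seasons = NULL, archetypes = NULL,
                       stages = c("simulate", "micromet", "sapflow",
                                  "vcurve", "analyze"),
                       reference_days = 21, psi_tolerance = 0.1,
                       n_vessels = 100, vpd_floor = 0.1) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 seasons = seasons, archetypes = archetypes,
                 stages = stages, reference_days = reference_days,
                 psi_tolerance = psi_tolerance,
                 n_vessels = as.integer(n_vessels), vpd_floor = vpd_floor),
            class = "run_config")
}

need_stage <- function(results, stage, wanted_by) {
  if (is.null(results[[stage]]))
    stop_domain("stage '%s' requires output of stage '%s', which did not run",
                wanted_by, stage)
  results[[stage]]
}

#' Run the full pipeline on synthetic scenarios
#'
#' Stages run in dependency order; each writes tidy CSVs under
#' `config$out_dir` and the run closes with a JSON manifest recording
#' seeds, parameters and per-stage row counts.
#'
#' @param config a [run_config()].
#' @return invisibly, a list of per-stage results plus `manifest`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 16)
  seasons <- config$seasons %||% list(
    dry = weather_config_dry(seed = seeds[1]),
    normal = weather_config_normal(seed = seeds[2]))
  archetypes <- config$archetypes %||%
    list(archetype_ericoid(), archetype_proteoid(), archetype_restioid())
  results <- list()
  manifest <- list(seed = config$seed, stages = list(),
                   parameters = list(reference_days = config$reference_days,
                                     psi_tolerance = config$psi_tolerance,
                                     n_vessels = config$n_vessels,
                                     vpd_floor = config$vpd_floor))

  if ("simulate" %in% config$stages) {
    sim <- list()
    for (sn in names(seasons)) {
      weather <- generate_weather(seasons[[sn]])
      plants <- lapply(seq_along(archetypes), function(i)
        generate_plant_series(archetypes[[i]], weather,
                              seed = seeds[2 + i]))
      names(plants) <- vapply(archetypes, `[[`, "", "name")
      sim[[sn]] <- list(weather = weather, plants = plants)
      write_table_csv(weather, file.path(config$out_dir,
                                         paste0("weather_", sn, ".csv")))
    }
    results$simulate <- sim
    manifest$stages$simulate <- list(
      seasons = names(seasons),
      rows = vapply(sim, function(s) nrow(s$weather), 0))
  }

  if ("micromet" %in% config$stages) {
    sim <- need_stage(results, "simulate", "micromet")
    met <- lapply(sim, function(s) {
      daily <- daily_summaries(s$weather)
      dew <- detect_dew_events(s$weather)
      list(daily = daily, dew = dew)
    })
    for (sn in names(met)) {
      write_table_csv(met[[sn]]$daily,
                      file.path(config$out_dir, paste0("daily_", sn, ".csv")))
      write_table_csv(met[[sn]]$dew,
                      file.path(config$out_dir, paste0("dew_", sn, ".csv")))
    }
    results$micromet <- met
    manifest$stages$micromet <- list(
      dew_events = vapply(met, function(m) nrow(m$dew), 0))
  }

  if ("sapflow" %in% config$stages) {
    sim <- need_stage(results, "simulate", "sapflow")
    sf <- list()
    for (sn in names(sim)) {
      weather <- sim[[sn]]$weather
      ref_win <- c(min(as.Date(weather$timestamp, tz = "UTC")),
                   min(as.Date(weather$timestamp, tz = "UTC")) +
                     config$reference_days - 1)
      sf[[sn]] <- lapply(sim[[sn]]$plants, function(p) {
        flux <- sap_flux_density(p$vh)
        daily <- normalize_to_reference(flux$daily, "total_js", ref_win)
        v <- vpd(weather$t_air, weather$rh)
        esf <- pmax(p$vh$vh, 0) * 1000  # identity-scale map to flux units
        g <- gsf(esf, v, weather$t_air, vpd_floor = config$vpd_floor)
        list(daily = daily, gsf = g, reference_window = ref_win)
      })
      for (sp in names(sf[[sn]]))
        write_table_csv(sf[[sn]][[sp]]$daily,
                        file.path(config$out_dir,
                                  sprintf("daily_js_%s_%s.csv", sp, sn)))
    }
    results$sapflow <- sf
    manifest$stages$sapflow <- list(reference_days = config$reference_days)
  }

  if ("vcurve" %in% config$stages) {
    curves <- list()
    for (i in seq_along(archetypes)) {
      ar <- archetypes[[i]]
      cfg <- stack_config(n_vessels = config$n_vessels,
                          a = ar$vulnerability_a, b = ar$vulnerability_b,
                          seed = seeds[8 + i])
      sim_stack <- generate_optical_stack(cfg)
      ov <- optical_vulnerability(sim_stack$stack, sim_stack$timeline)
      curves[[ar$name]] <- ov$curve
      write_table_csv(ov$cumulative,
                      file.path(config$out_dir,
                                paste0("embolism_", ar$name, ".csv")))
    }
    results$vcurve <- curves
    manifest$stages$vcurve <- list(
      p50 = vapply(curves, `[[`, 0, "b"),
      n_vessels = config$n_vessels)
  }

  if ("analyze" %in% config$stages) {
    sim <- need_stage(results, "simulate", "analyze")
    sf <- need_stage(results, "sapflow", "analyze")
    minima <- list(); recov <- list()
    for (sn in names(sim)) {
      obs <- do.call(rbind, lapply(sim[[sn]]$plants, `[[`, "psi"))
      obs$season <- sn
      minima[[sn]] <- min_water_potentials(obs)
      for (sp in names(sim[[sn]]$plants)) {
        p <- sim[[sn]]$plants[[sp]]
        truth <- p$daily_truth
        ref_win <- sf[[sn]][[sp]]$reference_window
        ref_pd <- mean(truth$psi_predawn[truth$date >= ref_win[1] &
                                           truth$date <= ref_win[2]])
        rr <- recovery_metric(sf[[sn]][[sp]]$daily, "total_js_pct",
                              data.frame(date = truth$date,
                                         psi = truth$psi_predawn),
                              ref_pd, tolerance = config$psi_tolerance,
                              species = sp, season = sn,
                              quantity = "total_daily_js")
        recov[[paste(sp, sn)]] <- data.frame(
          species = sp, season = sn, quantity = rr$quantity,
          recovery_percent = rr$recovery_percent,
          trigger_date = rr$trigger_date)
      }
    }
    minima_all <- do.call(rbind, minima)
    recovery_all <- do.call(rbind, recov)
    rownames(minima_all) <- rownames(recovery_all) <- NULL
    write_table_csv(minima_all, file.path(config$out_dir, "psi_minima.csv"))
    write_table_csv(recovery_all, file.path(config$out_dir, "recovery.csv"))
    results$analyze <- list(minima = minima_all, recovery = recovery_all)
    if (!is.null(results$vcurve)) {
      t2 <- table2_report(results$vcurve, minima_all)
      write_table_csv(t2, file.path(config$out_dir, "table2.csv"))
      results$analyze$table2 <- t2
    }
    manifest$stages$analyze <- list(rows = nrow(minima_all))
  }

  manifest$row_counts <- lapply(results, length)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Summary table of P50, safety margins and predicted seasonal loss
#'
#' One row per species x season: P50, the seasonal minimum water potential,
#' the hydraulic safety margin, and the predicted loss of xylem function
#' (vulnerability curve evaluated at the minimum, rounded to one decimal).
#'
#' @param curves named list of `vulnerability_curve` objects (names =
#'   species).
#' @param minima a [min_water_potentials()] table (the `period` used is
#'   `"predawn"` if present, otherwise all rows).
#' @param period which observation period supplies the minima
#'   (default `"predawn"`).
#' @return data frame: `species`, `season`, `psi_min`, `p50`,
#'   `safety_margin`, `predicted_loss`.
#' @export
table2_report <- function(curves, minima, period = "predawn") {
  if ("period" %in% names(minima) && period %in% minima$period)
    minima <- minima[minima$period == period, ]
  rows <- list()
  for (i in seq_len(nrow(minima))) {
    sp <- minima$species[i]
    if (is.null(curves[[sp]])) {
      warning(sprintf("no vulnerability curve for species '%s'; row omitted", sp))
      next
    }
    cv <- curves[[sp]]
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp, season = minima$season[i],
      psi_min = minima$min_psi[i], p50 = cv$b,
      safety_margin = safety_margin(minima$min_psi[i], min(cv$b, 0)),
      predicted_loss = predicted_loss(cv, minima$min_psi[i])$percent_rounded)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
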