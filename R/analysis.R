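# Seasonal and inter-specific inference: recovery after rehydration,
# minimum water potentials, AIC model selection with likelihood-ratio
# gating, one-way ANOVA with Tukey compact letter displays, and stomatal
# conductance / water potential envelopes.

#' Within-season recovery of a normalized daily series
#'
#' Recovery is the maximum percent-of-reference value attained on or after
#' the first date, following the seasonal water-potential minimum, at which
#' predawn water potential returned to its pre-stressed reference (within
#' `tolerance`).
#'
#' @param daily data frame with `date` and a `*_pct` column (see
#'   [normalize_to_reference()]).
#' @param pct_col name of the normalized column.
#' @param predawn data frame with `date` and `psi` (daily predawn means,
#'   MPa).
#' @param reference_predawn pre-stressed predawn water potential, MPa.
#' @param tolerance MPa; default 0.1.
#' @param species,season,quantity labels carried into the result.
#' @return list of class `recovery_result`: `recovery_percent`,
#'   `trigger_date` (NA if no rehydration occurred), `min_date`, labels.
#' @export
recovery_metric <- function(daily, pct_col, predawn, reference_predawn,
                            tolerance = 0.1, species = NA, season = NA,
                            quantity = pct_col) {
  stopifnot(all(c("date", "psi") %in% names(predawn)))
  min_date <- predawn$date[which.min(predawn$psi)]
  after <- predawn$date >= min_date
  ok <- after & predawn$psi >= reference_predawn - tolerance
  if (!any(ok)) {
    return(structure(list(recovery_percent = NA_real_,
                          trigger_date = as.Date(NA), min_date = min_date,
                          species = species, season = season,
                          quantity = quantity, rehydrated = FALSE),
                     class = "recovery_result"))
  }
  trigger <- min(predawn$date[ok])
  vals <- daily[[pct_col]][daily$date >= trigger]
  structure(list(recovery_percent = max(vals, na.rm = TRUE),
                 trigger_date = trigger, min_date = min_date,
                 species = species, season = season, quantity = quantity,
                 rehydrated = TRUE),
            class = "recovery_result")
}

#' Minimum water potentials by species, season and period
#'
#' For each species x season x period cell, averages individuals within
#' each campaign date, selects the most negative date mean, and reports it
#' with the standard error of that date's individuals.
#'
#' @param observations data frame with `date`, `individual_id`, `species`,
#'   `period` (`"predawn"`/`"midday"`), `psi` (MPa), and optionally
#'   `season`.
#' @return data frame: `species`, `season`, `period`, `min_psi`, `se`, `n`,
#'   `min_date`.
#' @export
min_water_potentials <- function(observations) {
  if (any(observations$psi > 0)) stop_domain("psi must be <= 0 MPa")
  if (is.null(observations$season)) observations$season <- "all"
  cells <- unique(observations[c("species", "season", "period")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- observations$species == cells$species[i] &
      observations$season == cells$season[i] &
      observations$period == cells$period[i]
    obs <- observations[sel, ]
    by_date <- split(obs$psi, obs$date)
    means <- vapply(by_date, mean, 0)
    k <- which.min(means)
    vals <- by_date[[k]]
    data.frame(species = cells$species[i], season = cells$season[i],
               period = cells$period[i], min_psi = means[k],
               se = stats::sd(vals) / sqrt(length(vals)),
               n = length(vals), min_date = as.Date(names(by_date)[k]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a model candidate for AIC comparison
#'
#' Wraps a fitted model (from `lm()` or `lme4::lmer()`) with a label.
#' Mixed models are refitted by maximum likelihood before any
#' likelihood-ratio comparison, as required when fixed effects differ.
#'
#' @param fit fitted model object.
#' @param label human-readable label.
#' @return object of class `model_candidate` with `label`, `fit`,
#'   `loglik`, `k` (parameter count) and `aic` (= 2k - 2 logLik).
#' @export
model_candidate <- function(fit, label) {
  if (inherits(fit, "merMod")) {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop_domain("lme4 is required for mixed-model candidates")
    if (lme4::isREML(fit)) fit <- lme4::refitML(fit)
  }
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  structure(list(label = label, fit = fit, loglik = as.numeric(ll),
                 k = k, aic = 2 * k - 2 * as.numeric(ll)),
            class = "model_candidate")
}

#' Select the best model by AIC with likelihood-ratio gating
#'
#' Ranks candidates by AIC and returns the lowest-AIC candidate that also
#' differs statistically (likelihood-ratio chi-square, p < `alpha`) from
#' every candidate nested within it that it beats. When the lowest-AIC
#' model is not significantly better than a simpler candidate, the simpler
#' candidate is preferred (ties in AIC break toward fewer parameters).
#'
#' @param candidates list of [model_candidate()] objects fitted to the same
#'   data.
#' @param alpha significance level (default 0.05).
#' @return list of class `model_selection`: `best` (a candidate), `table`
#'   (label, k, loglik, aic, delta_aic), and the pairwise LRT p-values.
#' @export
compare_models_aic <- function(candidates, alpha = 0.05) {
  stopifnot(length(candidates) >= 2,
            all(vapply(candidates, inherits, TRUE, "model_candidate")))
  aic <- vapply(candidates, `[[`, 0, "aic")
  k <- vapply(candidates, `[[`, 0, "k")
  ll <- vapply(candidates, `[[`, 0, "loglik")
  ord <- order(aic, k)  # AIC first, fewer parameters on ties
  # walk down the ranking: accept a model only if it is significantly
  # better than every simpler (nested) rival; otherwise fall through to
  # the simpler rival
  lrt_p <- function(i, j) {  # i complex, j simple
    stat <- 2 * (ll[i] - ll[j])
    df <- k[i] - k[j]
    if (df <= 0 || stat < 0) return(NA_real_)
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
  best <- ord[1]
  repeat {
    simpler <- which(k < k[best])
    if (!length(simpler)) break
    pvals <- vapply(simpler, function(j) lrt_p(best, j), 0)
    if (all(is.na(pvals))) break
    worst <- which.max(pvals)
    if (!is.na(pvals[worst]) && pvals[worst] >= alpha) {
      # not distinguishable from this simpler model: prefer it
      cand <- simpler[worst]
      if (cand == best) break
      best <- cand
    } else break
  }
  pm <- outer(seq_along(candidates), seq_along(candidates),
              Vectorize(function(i, j) if (k[i] > k[j]) lrt_p(i, j) else NA_real_))
  labels <- vapply(candidates, `[[`, "", "label")
  dimnames(pm) <- list(labels, labels)
  tab <- data.frame(label = labels[ord], k = k[ord], loglik = ll[ord],
                    aic = aic[ord], delta_aic = aic[ord] - min(aic))
  structure(list(best = candidates[[best]], table = tab, lrt_p = pm,
                 alpha = alpha),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection (lowest AIC that differs at p <", x$alpha, ")\n")
  print(x$table, row.names = FALSE)
  cat("Selected:", x$best$label, "\n")
  invisible(x)
}

# compact letter display by insert-and-absorb on a significance matrix
compact_letters <- function(groups, sig) {
  # sig[i, j] TRUE when groups i and j differ significantly
  n <- length(groups)
  absorb <- function(sets) {
    sets <- sets[lengths(sets) > 0]
    sets <- sets[order(-lengths(sets))]
    kept <- list()
    for (s in sets) {
      if (!any(vapply(kept, function(t) all(s %in% t), TRUE))) {
        kept[[length(kept) + 1L]] <- s
      }
    }
    kept
  }
  sets <- list(seq_len(n))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!sig[i, j]) next
    hit <- vapply(sets, function(s) i %in% s && j %in% s, TRUE)
    for (s in which(hit)) {
      sets <- append(sets, list(setdiff(sets[[s]], i),
                                setdiff(sets[[s]], j)))
    }
    sets <- absorb(sets[!c(hit, rep(FALSE, 2 * sum(hit)))])
  }
  letters_out <- vapply(seq_len(n), function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, TRUE))],
          collapse = "")
  }, "")
  names(letters_out) <- groups
  letters_out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' @param values numeric response.
#' @param group factor (or coercible) of group labels; every group needs at
#'   least 2 values.
#' @param alpha significance level (default 0.05).
#' @return list of class `anova_tukey`: `F`, `df` (c(between, within)),
#'   `p`, `tukey` (the pairwise table) and `letters` (groups sharing no
#'   letter differ at `alpha`).
#' @export
anova_tukey <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) stop_domain("need >= 2 groups")
  counts <- table(group)
  if (any(counts < 2))
    stop_domain("every group needs >= 2 values (group '%s' has %d)",
                names(counts)[which.min(counts)], min(counts))
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  lv <- levels(group)
  sig <- matrix(FALSE, nlevels(group), nlevels(group),
                dimnames = list(lv, lv))
  pairs <- strsplit(rownames(tuk), "-", fixed = TRUE)
  for (r in seq_along(pairs)) {
    gi <- pairs[[r]][1]; gj <- pairs[[r]][2]
    sig[gi, gj] <- sig[gj, gi] <- tuk[r, "p adj"] < alpha
  }
  structure(list(F = s[["F value"]][1],
                 df = c(s[["Df"]][1], s[["Df"]][2]),
                 p = s[["Pr(>F)"]][1],
                 tukey = tuk,
                 letters = compact_letters(lv, sig),
                 alpha = alpha),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("Letters:", paste(names(x$letters), x$letters, sep = ":",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Fit the assimilation response to stomatal conductance
#'
#' The A-gs relation is fitted as a saturating rectangular hyperbola
#' \eqn{A = A_{max} g_s / (K + g_s)} by nonlinear least squares
#' (default), or as a second-degree polynomial.
#'
#' @param gs stomatal conductance observations, mol m^-2 s^-1.
#' @param A carbon assimilation observations, umol m^-2 s^-1.
#' @param form `"hyperbola"` or `"polynomial"`.
#' @return list of class `gs_A_fit`: `form`, `coefficients`, `r_squared`
#'   and `predict` (a function of gs).
#' @export
fit_gs_A <- function(gs, A, form = c("hyperbola", "polynomial")) {
  form <- match.arg(form)
  if (length(gs) != length(A) || length(gs) < 4)
    stop_domain("need >= 4 paired (gs, A) observations")
  if (form == "hyperbola") {
    fit <- stats::nls(A ~ Amax * gs / (K + gs),
                      start = list(Amax = max(A), K = stats::median(gs)),
                      control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
    cf <- stats::coef(fit)
    pred <- function(x) cf[["Amax"]] * x / (cf[["K"]] + x)
  } else {
    fit <- stats::lm(A ~ gs + I(gs^2))
    cf <- stats::coef(fit)
    pred <- function(x) cf[[1]] + cf[[2]] * x + cf[[3]] * x^2
  }
  r2 <- 1 - sum((A - pred(gs))^2) / sum((A - mean(A))^2)
  structure(list(form = form, coefficients = cf, r_squared = r2,
                 predict = pred),
            class = "gs_A_fit")
}

#' Stomatal conductance / water potential envelope
#'
#' Pairs stomatal-conductance observations with midday water potentials by
#' species and campaign date, and reports the water potential at which
#' conductance falls to `closure_fraction` of its observed maximum
#' (linear interpolation along decreasing water potential).
#'
#' @param gs_obs data frame with `date`, `species`, `gs`.
#' @param psi_obs data frame with `date`, `species`, `psi` (midday, MPa).
#' @param closure_fraction fraction of maximum gs defining closure
#'   (default 0.1).
#' @return list of class `gs_psi_envelope`: `points` (date, species, psi,
#'   gs) and `closure_psi` (NA when gs never crosses the closure level).
#' @export
gs_psi_envelope <- function(gs_obs, psi_obs, closure_fraction = 0.1) {
  m <- merge(gs_obs, psi_obs, by = c("date", "species"))
  if (nrow(m) == 0) {
    warning("no overlapping species/date pairs; empty envelope")
    return(structure(list(points = m, closure_psi = NA_real_),
                     class = "gs_psi_envelope"))
  }
  m <- m[order(-m$psi), ]  # wet to dry
  gmax <- max(m$gs)
  closure <- closure_fraction * gmax
  below <- which(m$gs <= closure)
  closure_psi <- NA_real_
  if (length(below) && diff(range(m$gs)) > 0) {
    k <- below[1]
    if (k > 1) {
      # interpolate between the last open and first closed point
      closure_psi <- m$psi[k - 1] + (m$psi[k] - m$psi[k - 1]) *
        (m$gs[k - 1] - closure) / (m$gs[k - 1] - m$gs[k])
    } else closure_psi <- m$psi[k]
  }
  structure(list(points = m[c("date", "species", "psi", "gs")],
                 closure_psi = closure_psi,
                 closure_fraction = closure_fraction),
            class = "gs_psi_envelope")
}
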