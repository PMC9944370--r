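# Recovery metrics, minima, AIC selection, ANOVA + Tukey letters,
# conductance/water-potential envelopes.

make_panel <- function() {
  dates <- as.Date("2013-01-01") + 0:99
  pd <- c(seq(-0.3, -3, length.out = 60), seq(-3, -0.35, length.out = 40))
  pct <- c(seq(100, 10, length.out = 60), seq(10, 67, length.out = 40))
  list(daily = data.frame(date = dates, q_pct = pct),
       predawn = data.frame(date = dates, psi = pd))
}

test_that("recovery is the max normalized value after rehydration", {
  p <- make_panel()
  r <- recovery_metric(p$daily, "q_pct", p$predawn, reference_predawn = -0.3,
                       tolerance = 0.1)
  expect_true(r$rehydrated)
  # brute-force oracle: first post-minimum date within tolerance, then max
  min_d <- p$predawn$date[which.min(p$predawn$psi)]
  ok <- p$predawn$date >= min_d & p$predawn$psi >= -0.3 - 0.1
  trig <- min(p$predawn$date[ok])
  expect_equal(r$trigger_date, trig)
  expect_equal(r$recovery_percent, max(p$daily$q_pct[p$daily$date >= trig]))
  expect_equal(r$recovery_percent, 67)

  # a series returning to its reference recovers to 100
  p2 <- make_panel()
  p2$daily$q_pct[100] <- 100
  expect_equal(recovery_metric(p2$daily, "q_pct", p2$predawn, -0.3)$recovery_percent,
               100)

  # infinite tolerance triggers at the minimum date itself: global max after it
  r3 <- recovery_metric(p$daily, "q_pct", p$predawn, -0.3, tolerance = Inf)
  expect_equal(r3$trigger_date, min_d)

  # no rehydration: flagged absent, not an error
  dry <- data.frame(date = p$predawn$date,
                    psi = seq(-0.3, -4, length.out = 100))
  r4 <- recovery_metric(p$daily, "q_pct", dry, -0.3)
  expect_false(r4$rehydrated)
  expect_true(is.na(r4$recovery_percent))
})

test_that("minimum water potentials pick the most negative date mean", {
  obs <- data.frame(
    date = rep(as.Date(c("2013-01-01", "2013-02-01")), each = 3),
    individual_id = rep(paste0("i", 1:3), 2),
    species = "sp", period = "midday",
    psi = c(-1.0, -1.1, -0.9, -2.0, -2.2, -1.8))
  m <- min_water_potentials(obs)
  expect_equal(nrow(m), 1)
  expect_equal(m$min_psi, -2.0)
  expect_equal(m$se, sd(c(-2.0, -2.2, -1.8)) / sqrt(3))
  expect_equal(m$min_date, as.Date("2013-02-01"))
  expect_equal(m$n, 3)

  # single date: that date's mean
  m1 <- min_water_potentials(obs[obs$date == obs$date[1], ])
  expect_equal(m1$min_psi, mean(c(-1.0, -1.1, -0.9)))

  # synthetic panel against a brute-force scan over all cells
  set.seed(3)
  panel <- expand.grid(date = as.Date("2013-01-01") + seq(0, 90, 15),
                       individual_id = paste0("i", 1:5),
                       species = c("A", "B"),
                       period = c("predawn", "midday"))
  panel$psi <- -runif(nrow(panel), 0.2, 4)
  panel$season <- ifelse(panel$date < as.Date("2013-02-15"), "s1", "s2")
  m2 <- min_water_potentials(panel)
  for (i in seq_len(nrow(m2))) {
    sub <- panel[panel$species == m2$species[i] & panel$season == m2$season[i] &
                   panel$period == m2$period[i], ]
    mins <- tapply(sub$psi, sub$date, mean)
    expect_equal(m2$min_psi[i], min(mins))
  }
  expect_error(min_water_potentials(transform(obs, psi = abs(psi))), "<= 0")
})

test_that("AIC selection demands a significant improvement over simpler rivals", {
  set.seed(10)
  n <- 120
  x <- runif(n); z <- runif(n)
  y <- 2 * x + rnorm(n)
  full <- model_candidate(lm(y ~ x + z), "full")
  red <- model_candidate(lm(y ~ x), "reduced")
  # aic field consistency
  for (cand in list(full, red))
    expect_equal(cand$aic, 2 * cand$k - 2 * cand$loglik)
  # z is noise: the reduced model must win even if AIC is close
  sel <- compare_models_aic(list(full, red))
  expect_equal(sel$best$label, "reduced")
  expect_error(compare_models_aic(list(full)), "2")
})

test_that("AIC selection has power and type-I control on simulated panels", {
  sim_once <- function(interaction, seed) {
    set.seed(seed)
    n <- 200
    species <- factor(sample(c("A", "B"), n, TRUE))
    season <- factor(sample(c("dry", "normal"), n, TRUE))
    mu <- 1 + 0.5 * (species == "B") + 0.5 * (season == "normal") +
      interaction * (species == "B") * (season == "normal")
    y <- mu + rnorm(n, 0, 0.5)
    full <- model_candidate(lm(y ~ species * season), "interaction")
    main <- model_candidate(lm(y ~ species + season), "main-effects")
    compare_models_aic(list(full, main))$best$label
  }
  alt <- vapply(1:100, function(s) sim_once(1, 400 + s), "")
  expect_gte(mean(alt == "interaction"), 0.9)
  null <- vapply(1:100, function(s) sim_once(0, 800 + s), "")
  expect_gte(mean(null == "main-effects"), 0.9)
})

test_that("anova_tukey letters partition groups consistently", {
  set.seed(5)
  # two statistically identical groups share a letter
  v <- rnorm(20); g <- rep(c("a", "b"), each = 10)
  res <- anova_tukey(v + 0 * (g == "b"), g)
  expect_lt(res$F, 4)
  expect_equal(unname(res$letters["a"]), unname(res$letters["b"]))

  # three well-separated groups get three distinct letters
  v3 <- c(rnorm(10, 0), rnorm(10, 10), rnorm(10, 20))
  g3 <- rep(c("lo", "mid", "hi"), each = 10)
  res3 <- anova_tukey(v3, g3)
  expect_lt(res3$p, 1e-6)
  expect_equal(length(unique(res3$letters)), 3)

  # grand-mean invariance
  res3b <- anova_tukey(v3 + 100, g3)
  expect_equal(res3b$F, res3$F)
  expect_identical(res3b$letters, res3$letters)

  # letters are a valid partition: no shared letter implies pairwise p < alpha
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(3:5, 1)
    vv <- rnorm(12 * k, mean = rep(runif(k, 0, 3), each = 12))
    gg <- rep(letters[1:k], each = 12)
    r <- anova_tukey(vv, gg)
    pairs <- strsplit(rownames(r$tukey), "-", fixed = TRUE)
    for (j in seq_along(pairs)) {
      shared <- intersect(strsplit(r$letters[pairs[[j]][1]], "")[[1]],
                          strsplit(r$letters[pairs[[j]][2]], "")[[1]])
      if (length(shared) == 0)
        expect_lt(r$tukey[j, "p adj"], r$alpha)
    }
  }

  expect_error(anova_tukey(c(1, 2, 3), c("a", "a", "b")), "2 values")
  expect_error(anova_tukey(1:4, rep("a", 4)), "2 groups")
})

test_that("gs-A response fits recover a generating hyperbola", {
  set.seed(12)
  gs <- runif(40, 0.01, 0.4)
  A <- 20 * gs / (0.1 + gs) + rnorm(40, 0, 0.2)
  fit <- fit_gs_A(gs, A)
  expect_equal(unname(fit$coefficients["Amax"]), 20, tolerance = 0.1)
  expect_equal(unname(fit$coefficients["K"]), 0.1, tolerance = 0.15)
  expect_gt(fit$r_squared, 0.95)
  poly <- fit_gs_A(gs, A, form = "polynomial")
  expect_gt(poly$r_squared, 0.8)
  expect_error(fit_gs_A(gs[1:3], A[1:3]), "4")
})

test_that("gs-psi envelopes locate the stomatal closure threshold", {
  dates <- as.Date("2013-01-01") + 0:20
  psi <- seq(0, -2, length.out = 21)
  gs <- pmax(0.3 * (1 + psi / 2), 0)  # linear closure reaching 0 at -2 MPa
  env <- gs_psi_envelope(data.frame(date = dates, species = "sp", gs = gs),
                         data.frame(date = dates, species = "sp", psi = psi))
  expect_equal(nrow(env$points), 21)
  expect_equal(env$closure_psi, -1.8, tolerance = 0.01)

  # constant conductance: closure undefined
  env2 <- gs_psi_envelope(data.frame(date = dates, species = "sp", gs = 0.3),
                          data.frame(date = dates, species = "sp", psi = psi))
  expect_true(is.na(env2$closure_psi))

  # disjoint dates: empty result with a warning
  expect_warning(
    env3 <- gs_psi_envelope(data.frame(date = dates, species = "sp", gs = gs),
                            data.frame(date = dates + 400, species = "sp",
                                       psi = psi)),
    "overlap")
  expect_equal(nrow(env3$points), 0)
})
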