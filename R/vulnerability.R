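# Optical xylem vulnerability: frame differencing, embolism-event
# detection and counting, cumulative percent embolism, sigmoid curve
# fitting, P50, safety margins and predicted in-situ loss of function.
#
# The vulnerability model throughout is the two-parameter sigmoid
#   PE(psi) = 100 - 100 / (1 + exp(a * (psi - b)))
# with a < 0 (MPa^-1, sensitivity) and b = P50 (MPa). Psi is always in MPa
# and negative under tension; positive "tension-unit" inputs are rejected.

#' Percent embolism predicted by the sigmoid vulnerability model
#'
#' @param psi xylem water potential, MPa (<= 0).
#' @param a slope parameter, MPa^-1 (negative).
#' @param b water potential at 50 percent embolism (P50), MPa.
#' @return percent embolism in \[0, 100\]; exactly 50 at `psi = b`.
#' @export
percent_embolism <- function(psi, a, b) {
  check_number(psi, "psi")
  100 - 100 / (1 + exp(a * (psi - b)))
}

#' Solve the sigmoid slope from one (psi, percent) anchor
#'
#' Inverts the vulnerability sigmoid for `a` given P50 and a single
#' observed (water potential, percent embolism) pair. Used to calibrate a
#' species' curve from a printed percent-loss value.
#'
#' @param psi anchor water potential, MPa.
#' @param percent anchor percent embolism, strictly inside (0, 100).
#' @param b P50, MPa; must differ from `psi`.
#' @return slope `a`, MPa^-1.
#' @export
solve_sigmoid_slope <- function(psi, percent, b) {
  if (percent <= 0 || percent >= 100)
    stop_domain("percent must be strictly inside (0, 100) to solve for a")
  if (psi == b) stop_domain("psi equal to b leaves a unidentified")
  # percent = 100 - 100/(1 + e^{a(psi-b)})  =>  e^{a(psi-b)} = p/(100-p)
  log(percent / (100 - percent)) / (psi - b)
}

#' Construct an image stack
#'
#' @param frames list of integer/numeric matrices of identical dimensions,
#'   one per scan; grey levels in \[0, 255\].
#' @param timestamps POSIXct vector, one per frame, strictly increasing.
#' @param sample_id label.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, timestamps, sample_id = "sample") {
  if (length(frames) < 2) stop_domain("an image stack needs >= 2 frames")
  if (length(frames) != length(timestamps))
    stop_domain("one timestamp per frame required")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_domain("all frames must share one shape")
  check_increasing_time(timestamps)
  structure(list(frames = frames, timestamps = timestamps,
                 sample_id = sample_id),
            class = "image_stack")
}

#' Difference stack from consecutive frames
#'
#' Absolute difference of consecutive frames after per-frame mean
#' normalization (each frame is shifted to zero mean before subtraction, so
#' slow global illumination drift does not register as change). N frames in,
#' N-1 difference frames out; difference frame i is |frame(i+1) - frame(i)|.
#'
#' @param stack an [image_stack()].
#' @param normalize shift each frame to zero mean first (default TRUE).
#' @return list with `frames` (N-1 matrices) and `timestamps` (those of the
#'   later frame of each pair).
#' @export
difference_images <- function(stack, normalize = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  f <- stack$frames
  if (normalize) f <- lapply(f, function(m) m - mean(m))
  diffs <- lapply(seq_len(length(f) - 1L),
                  function(i) abs(f[[i + 1L]] - f[[i]]))
  list(frames = diffs, timestamps = stack$timestamps[-1L])
}

# 8-connected component labelling of a logical matrix, returned as a list
# of pixel-index vectors. Operates on the sparse set of TRUE pixels.
label_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  nr <- nrow(mask)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  key <- paste(row, col)
  lookup <- seq_along(idx)
  names(lookup) <- key
  seen <- rep(FALSE, length(idx))
  comps <- list()
  for (s in seq_along(idx)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer()
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      members <- c(members, idx[cur])
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nb <- lookup[paste(row[cur] + dr, col[cur] + dc)]
        if (!is.na(nb) && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

#' Detect embolism events in a difference stack
#'
#' Thresholds each difference frame, groups supra-threshold pixels by
#' 8-connectivity, discards clusters smaller than `min_cluster_px` as noise,
#' and never re-counts a pixel that embolized in an earlier frame.
#'
#' The default threshold is `mean + 5 sd` of the first `baseline_frames`
#' difference frames, mirroring a baseline-noise calibration, floored at
#' `threshold_floor` grey levels: per-frame mean normalization leaves a
#' small uniform residue on the background of frames in which several
#' events fire at once, and the floor keeps a quiet baseline from pushing
#' the threshold into that residue. Pass `intensity_threshold` to override
#' both.
#'
#' @param diffs result of [difference_images()].
#' @param intensity_threshold grey-level threshold; `NULL` for the baseline
#'   default.
#' @param min_cluster_px minimum cluster size in pixels (default 10).
#' @param baseline_frames frames used for the default threshold (default 10).
#' @param threshold_floor minimum default threshold, grey levels
#'   (default 20).
#' @return object of class `embolism_event_map`: per-frame lists of new
#'   pixel indices (`new_pixels`), per-frame counts of events and pixels,
#'   `timestamps`, `total_pixels` embolized, and the threshold used.
#' @export
detect_embolism_events <- function(diffs, intensity_threshold = NULL,
                                   min_cluster_px = 10,
                                   baseline_frames = 10,
                                   threshold_floor = 20) {
  if (min_cluster_px < 1) stop_domain("min_cluster_px must be >= 1")
  if (is.null(intensity_threshold)) {
    nb <- min(baseline_frames, length(diffs$frames))
    base <- unlist(diffs$frames[seq_len(nb)])
    intensity_threshold <- mean(base) + 5 * stats::sd(base)
    if (!is.finite(intensity_threshold))
      intensity_threshold <- threshold_floor
    intensity_threshold <- max(intensity_threshold, threshold_floor)
  }
  if (intensity_threshold <= 0)
    stop_domain("intensity_threshold must be positive")
  shape <- dim(diffs$frames[[1]])
  embolized <- matrix(FALSE, shape[1], shape[2])
  new_pixels <- vector("list", length(diffs$frames))
  n_events <- integer(length(diffs$frames))
  n_pixels <- integer(length(diffs$frames))
  for (i in seq_along(diffs$frames)) {
    mask <- diffs$frames[[i]] > intensity_threshold & !embolized
    comps <- label_components(mask)
    comps <- comps[lengths(comps) >= min_cluster_px]
    px <- unlist(comps) %||% integer()
    new_pixels[[i]] <- as.integer(px)
    n_events[i] <- length(comps)
    n_pixels[i] <- length(px)
    embolized[px] <- TRUE
  }
  structure(list(new_pixels = new_pixels, n_events = n_events,
                 n_pixels = n_pixels, timestamps = diffs$timestamps,
                 total_pixels = sum(n_pixels),
                 intensity_threshold = intensity_threshold,
                 min_cluster_px = min_cluster_px),
            class = "embolism_event_map")
}

#' Time-resolved cumulative percent embolism
#'
#' Converts per-frame embolized-pixel counts to a cumulative percentage of
#' all pixels that embolized during the run. Non-decreasing; ends at 100.
#'
#' @param events an [detect_embolism_events()] result.
#' @return data frame with `timestamp`, `new_pixels`, `cum_pixels`,
#'   `percent`.
#' @export
cumulative_embolism <- function(events) {
  stopifnot(inherits(events, "embolism_event_map"))
  if (events$total_pixels == 0)
    stop_domain("no embolism events: percent embolism is undefined")
  cum <- cumsum(events$n_pixels)
  data.frame(timestamp = events$timestamps,
             new_pixels = events$n_pixels,
             cum_pixels = cum,
             percent = 100 * cum / events$total_pixels)
}

#' Water potential at an arbitrary time from a psychrometer timeline
#'
#' Linear interpolation between bracketing observations; times outside the
#' recorded span raise an error rather than extrapolating.
#'
#' @param timeline data frame with `timestamp` (POSIXct) and `psi` (MPa,
#'   <= 0).
#' @param t POSIXct time(s) at which to evaluate.
#' @return water potential(s), MPa.
#' @export
psi_at_time <- function(timeline, t) {
  check_increasing_time(timeline$timestamp)
  if (any(timeline$psi > 0))
    stop_domain("psi must be <= 0 MPa (tension-positive input rejected)")
  tn <- as.numeric(t)
  span <- range(as.numeric(timeline$timestamp))
  if (any(tn < span[1] | tn > span[2]))
    stop_domain("requested time outside the psi timeline; not extrapolating")
  stats::approx(as.numeric(timeline$timestamp), timeline$psi, xout = tn,
                method = "linear", ties = "ordered")$y
}

#' Fit the sigmoid vulnerability curve
#'
#' Nonlinear least squares of percent embolism on water potential under the
#' two-parameter sigmoid. `b` is initialized at the linearly interpolated
#' 50 percent crossing and `a` at -1; up to `n_restarts` jittered restarts
#' are attempted before declaring non-convergence.
#'
#' @param psi water potentials, MPa (<= 0).
#' @param percent percent embolism in \[0, 100\].
#' @param n_restarts jittered restarts after the deterministic start
#'   (default 5).
#' @return object of class `vulnerability_curve`: `a`, `b` (= P50),
#'   `fit_residual` (sum of squared residuals), `n`, and the source points.
#' @export
fit_vulnerability_curve <- function(psi, percent, n_restarts = 5) {
  if (length(psi) != length(percent)) stop_domain("psi and percent must pair")
  if (length(psi) < 5) stop_domain("need >= 5 (psi, percent) points")
  if (any(psi > 0)) stop_domain("psi must be <= 0 MPa")
  if (diff(range(percent)) <= 20)
    stop_domain("degenerate curve: points span <= 20 percentage points")
  ord <- order(psi, decreasing = TRUE)  # from wet to dry
  b0 <- stats::approx(percent[ord], psi[ord], xout = 50, ties = "ordered",
                      rule = 2)$y
  sse <- function(p) {
    pred <- percent_embolism(psi, p[1], p[2])
    sum((percent - pred)^2)
  }
  starts <- rbind(c(-1, b0))
  set.seed_local <- function(i) c(-exp(stats::runif(1, -1.5, 1.5)),
                                  b0 + stats::rnorm(1, 0, 0.5))
  best <- NULL
  for (i in seq_len(1 + n_restarts)) {
    p0 <- if (i == 1) starts[1, ] else set.seed_local(i)
    fit <- tryCatch(
      stats::optim(p0, sse, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$par[1] < 0 &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop_domain("vulnerability fit failed to converge after %d restarts (%d points, percent range %.1f-%.1f)",
                n_restarts, length(psi), min(percent), max(percent))
  # polish with Newton-quality local optimizer
  pol <- tryCatch(stats::optim(best$par, sse, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-14)),
                  error = function(e) best)
  if (pol$value <= best$value && pol$par[1] < 0) best <- pol
  structure(list(a = best$par[1], b = best$par[2],
                 fit_residual = best$value, n = length(psi),
                 source_points = data.frame(psi = psi, percent = percent)),
            class = "vulnerability_curve")
}

#' @export
print.vulnerability_curve <- function(x, ...) {
  cat(sprintf("Vulnerability curve: a = %.3f MPa^-1, P50 = %.2f MPa (n = %d, SSE = %.3g)\n",
              x$a, x$b, x$n, x$fit_residual))
  invisible(x)
}

#' Species-level curve from several individuals
#'
#' Default pools by averaging fitted parameters across individuals
#' (`mean-params`); `pooled-fit` refits one curve to all source points.
#'
#' @param curves list of [fit_vulnerability_curve()] results.
#' @param pooling `"mean-params"` or `"pooled-fit"`.
#' @return a `vulnerability_curve` (with `se_a`, `se_b` for mean-params).
#' @export
species_curve <- function(curves, pooling = c("mean-params", "pooled-fit")) {
  pooling <- match.arg(pooling)
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "vulnerability_curve")))
  if (pooling == "pooled-fit") {
    pts <- do.call(rbind, lapply(curves, `[[`, "source_points"))
    return(fit_vulnerability_curve(pts$psi, pts$percent))
  }
  a <- vapply(curves, `[[`, 0, "a"); b <- vapply(curves, `[[`, 0, "b")
  structure(list(a = mean(a), b = mean(b),
                 se_a = stats::sd(a) / sqrt(length(a)),
                 se_b = stats::sd(b) / sqrt(length(b)),
                 fit_residual = NA_real_, n = length(curves),
                 source_points = NULL),
            class = "vulnerability_curve")
}

#' Predicted in-situ loss of xylem function
#'
#' Evaluates a vulnerability curve at the seasonal minimum in-situ water
#' potential. Reported raw and rounded to one decimal (half up), matching
#' the convention of printed summary tables.
#'
#' @param curve a `vulnerability_curve`, or a list with `a` and `b`.
#' @param psi_min minimum in-situ water potential, MPa (<= 0).
#' @return list with `percent` (raw) and `percent_rounded`.
#' @export
predicted_loss <- function(curve, psi_min) {
  if (any(psi_min > 0)) stop_domain("psi_min must be <= 0 MPa")
  p <- percent_embolism(psi_min, curve$a, curve$b)
  list(percent = p, percent_rounded = round_half_up(p, 1))
}

#' Hydraulic safety margin
#'
#' `psi_min - P50` in MPa: positive when the plant's minimum water potential
#' stays less negative than its P50, negative when the P50 threshold was
#' crossed.
#'
#' @param psi_min minimum in-situ water potential, MPa (<= 0).
#' @param p50 water potential at 50 percent embolism, MPa (<= 0).
#' @return margin, MPa.
#' @export
safety_margin <- function(psi_min, p50) {
  if (any(psi_min > 0) || any(p50 > 0))
    stop_domain("psi_min and p50 must be <= 0 MPa")
  psi_min - p50
}

#' Full optical vulnerability workflow for one sample
#'
#' Difference imaging, event detection, cumulative percent embolism,
#' water-potential assignment via the psychrometer timeline, and sigmoid
#' fitting, in one call.
#'
#' @param stack an [image_stack()].
#' @param timeline psi timeline data frame (`timestamp`, `psi`).
#' @param intensity_threshold,min_cluster_px passed to
#'   [detect_embolism_events()].
#' @return list with `events`, `cumulative` (with a `psi` column) and
#'   `curve`.
#' @export
optical_vulnerability <- function(stack, timeline, intensity_threshold = NULL,
                                  min_cluster_px = 10) {
  diffs <- difference_images(stack)
  events <- detect_embolism_events(diffs, intensity_threshold, min_cluster_px)
  cum <- cumulative_embolism(events)
  cum$psi <- psi_at_time(timeline, cum$timestamp)
  pts <- cum[cum$new_pixels > 0, ]
  curve <- fit_vulnerability_curve(pts$psi, pts$percent)
  list(events = events, cumulative = cum, curve = curve)
}
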