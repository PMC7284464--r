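# Thermal-imaging verification: camera geometry, rotation-synchronised
# movie rendering and unwrapping, per-pixel endpoint detection, and
# endpoint-distribution comparison.

#' Thermal camera specification
#'
#' @param d_w camera-to-vial distance, m (default 0.15).
#' @param alpha field-of-view angle, degrees (default 45.1).
#' @param rpm vial rotation rate, revolutions per minute (default 5).
#' @param frames_per_rev frames recorded per revolution (integer >= 1); the
#'   frame rate is synchronised to the rotation, `rate = rpm/60 * k`.
#' @param noise_sd additive temperature noise, degrees C.
#' @param strip_width rendered frame width in azimuth strips (odd).
#' @return object of class `thermal_camera_spec`.
#' @export
thermal_camera_spec <- function(d_w = 0.15, alpha = 45.1, rpm = 5,
                                frames_per_rev = 16L, noise_sd = 0,
                                strip_width = 5L) {
  if (d_w <= 0) stop("d_w must be > 0")
  if (alpha <= 0 || alpha >= 180) stop("alpha must be in (0, 180) degrees")
  k <- frames_per_rev
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("frames_per_rev must be an integer >= 1")
  if (strip_width %% 2L != 1L) stop("strip_width must be odd")
  structure(list(d_w = d_w, alpha = alpha, rpm = rpm,
                 frames_per_rev = as.integer(round(k)),
                 frame_rate = rpm / 60 * k,
                 noise_sd = noise_sd, strip_width = as.integer(strip_width)),
            class = "thermal_camera_spec")
}

#' Horizontal field of view of the thermal camera
#'
#' `HFOV = 2 * d_w * tan(alpha / 2)` with the field-of-view angle in
#' degrees: sets the pixel-to-metre scale of the vial-surface maps.
#'
#' @param d_w camera-to-vial distance, m.
#' @param alpha field-of-view angle, degrees, in `(0, 180)`.
#' @return field of view, m.
#' @examples
#' hfov(0.15, 45.1)  # ~0.125 m
#' @export
hfov <- function(d_w, alpha) {
  if (any(alpha <= 0) || any(alpha >= 180))
    stop("alpha must be in (0, 180) degrees")
  if (any(d_w <= 0)) stop("d_w must be > 0")
  2 * d_w * tan(alpha / 2 * pi / 180)
}

#' Render a thermal movie from an endpoint map
#'
#' Emulates the verification camera watching the slowly rotating vial: each
#' surface element sits at a cold plateau while its coordinate still holds
#' ice, then ramps toward the heater temperature once its local primary
#' drying ends. Frame `j` (0-based) views azimuth strip `j mod k` at its
#' centre column; neighbouring columns show neighbouring strips.
#'
#' @param t_end_h matrix `[k, n_h]` of endpoint times in hours (azimuth
#'   resolution must equal `frames_per_rev`; use [spatial_bin()] or index
#'   resampling to get there).
#' @param camera a [thermal_camera_spec()].
#' @param plateau,heater plateau and heater temperatures, degrees C.
#' @param ramp_rate post-endpoint heating rate, degrees C per s.
#' @param duration movie length, s (default 1.15 x the latest endpoint).
#' @param seed seed for the noise draw.
#' @return object of class `thermal_movie`: list with `frames` (array
#'   `[n_h, strip_width, n_frames]`), `times` (s), `camera`, `t_end_h`.
#' @export
make_thermal_movie <- function(t_end_h, camera = thermal_camera_spec(),
                               plateau = -25, heater = 40, ramp_rate = 0.5,
                               duration = NULL, seed = 1L) {
  stopifnot(inherits(camera, "thermal_camera_spec"))
  k <- camera$frames_per_rev
  if (nrow(t_end_h) != k)
    stop(sprintf("t_end_h must have %d azimuth rows (= frames_per_rev)", k))
  n_h <- ncol(t_end_h)
  t_end_s <- t_end_h * 3600
  if (is.null(duration)) duration <- 1.15 * max(t_end_s, na.rm = TRUE)
  n_frames <- ceiling(duration * camera$frame_rate)
  times <- (seq_len(n_frames) - 1L) / camera$frame_rate
  w <- camera$strip_width
  half <- (w - 1L) %/% 2L
  frames <- array(NA_real_, c(n_h, w, n_frames))
  for (jf in seq_len(n_frames)) {
    t <- times[jf]
    for (c in seq_len(w)) {
      az <- ((jf - 1L) + (c - half - 1L)) %% k + 1L
      te <- t_end_s[az, ]
      temp <- ifelse(t < te, plateau,
                     pmin(plateau + ramp_rate * (t - te), heater))
      frames[, c, jf] <- temp
    }
  }
  if (camera$noise_sd > 0)
    frames <- frames + with_seed(seed,
      array(stats::rnorm(length(frames), 0, camera$noise_sd), dim(frames)))
  structure(list(frames = frames, times = times, camera = camera,
                 t_end_h = t_end_h),
            class = "thermal_movie")
}

#' Unwrap a rotation-synchronised thermal movie into per-pixel traces
#'
#' Takes the centre vertical strip of every frame (the face nearest the
#' optical axis, minimal perspective distortion) and assigns it to azimuth
#' `2*pi*(j mod k)/k`; every `(Phi, h)` pixel then carries one temperature
#' sample per revolution, i.e. a sampling period of `60/rpm` seconds.
#'
#' @param movie a `thermal_movie` (or any array `[n_h, w, n_frames]` plus
#'   `times`).
#' @param camera a [thermal_camera_spec()]; defaults to the movie's.
#' @return object of class `temperature_traces`: list with `temp` (array
#'   `[n_rev, k, n_h]`), `time` (matrix `[n_rev, k]`, s), `period` (s).
#' @export
unwrap_movie <- function(movie, camera = NULL) {
  stopifnot(inherits(movie, "thermal_movie"))
  if (is.null(camera)) camera <- movie$camera
  k <- camera$frames_per_rev
  if (abs(camera$frame_rate * 60 / camera$rpm - k) > 1e-9)
    stop("unwrap_movie: frame rate is not an integer number of frames per revolution")
  n_frames <- dim(movie$frames)[3L]
  n_h <- dim(movie$frames)[1L]
  centre <- (dim(movie$frames)[2L] + 1L) %/% 2L
  n_rev <- n_frames %/% k
  temp <- array(NA_real_, c(n_rev, k, n_h))
  time <- matrix(NA_real_, n_rev, k)
  for (r in seq_len(n_rev)) for (a in seq_len(k)) {
    jf <- (r - 1L) * k + a
    temp[r, a, ] <- movie$frames[, centre, jf]
    time[r, a] <- movie$times[jf]
  }
  structure(list(temp = temp, time = time, period = 60 / camera$rpm,
                 k = k, n_h = n_h),
            class = "temperature_traces")
}

#' Detect the primary-drying endpoint in one temperature trace
#'
#' Default policy: the endpoint is the first time the (lightly smoothed)
#' forward temperature difference exceeds the baseline rate by `K` robust
#' standard deviations, the baseline being the first quartile of the record
#' in time. A sharp post-drying temperature rise triggers immediately; a
#' flat trace stays undetected (`NA`).
#'
#' @param temp temperature samples, degrees C.
#' @param time sample times, s (uniform).
#' @param K threshold in robust baseline-rate SDs (default 5).
#' @param smooth running-mean half-width in samples (default 1: width 3).
#' @param min_rise absolute rate floor, degrees C per sample (guards the
#'   noiseless case where the robust SD is zero).
#' @return detected endpoint time, s, or `NA` if no rise is found.
#' @export
detect_endpoint <- function(temp, time, K = 5, smooth = 1L, min_rise = 0.5) {
  n <- length(temp)
  if (n < 10L) stop("detect_endpoint: need at least 10 samples")
  sm <- as.numeric(stats::filter(temp, rep(1 / (2 * smooth + 1),
                                           2 * smooth + 1), sides = 2))
  sm[is.na(sm)] <- temp[is.na(sm)]
  d <- diff(sm)
  base_n <- max(4L, floor(n / 4))
  base <- d[seq_len(min(base_n, length(d)))]
  thr <- stats::median(base) + pmax(K * stats::mad(base), min_rise)
  hit <- which(d > thr)
  if (!length(hit)) return(NA_real_)
  time[hit[1L]]
}

#' Detect endpoints for every pixel of unwrapped traces
#'
#' @param traces a `temperature_traces` object from [unwrap_movie()].
#' @param ... passed to [detect_endpoint()].
#' @return matrix `[k, n_h]` of endpoint times in hours (`NA` undetected).
#' @export
detect_endpoint_map <- function(traces, ...) {
  stopifnot(inherits(traces, "temperature_traces"))
  out <- matrix(NA_real_, traces$k, traces$n_h)
  for (a in seq_len(traces$k)) for (hh in seq_len(traces$n_h)) {
    out[a, hh] <- detect_endpoint(traces$temp[, a, hh],
                                  traces$time[, a], ...) / 3600
  }
  out
}

# index-resample a matrix to target dims by block mean (general ratios)
resample_map <- function(x, dims) {
  g1 <- floor((seq_len(nrow(x)) - 1L) * dims[1L] / nrow(x)) + 1L
  g2 <- floor((seq_len(ncol(x)) - 1L) * dims[2L] / ncol(x)) + 1L
  out <- matrix(NA_real_, dims[1L], dims[2L])
  for (j in seq_len(dims[2L])) for (i in seq_len(dims[1L])) {
    out[i, j] <- mean(x[g1 == i, g2 == j, drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Compare predicted and measured endpoint maps
#'
#' Aligns the two maps to the coarser grid (block means), then summarises
#' agreement: histograms, empirical CDFs, 5/50/95% quantiles, Pearson
#' correlation between aligned maps, and the maximum CDF distance
#' (two-sample Kolmogorov-Smirnov statistic).
#'
#' @param predicted,measured endpoint matrices in hours (or `endpoint_map`
#'   objects).
#' @param n_bins histogram bin count (default 30).
#' @return list of class `endpoint_comparison` with `correlation`,
#'   `max_cdf_distance`, `quantiles` (matrix), `histogram` (data.frame),
#'   `aligned` (the two aligned matrices), `median_abs_diff_h`.
#' @export
compare_endpoint_maps <- function(predicted, measured, n_bins = 30L) {
  p <- if (inherits(predicted, "endpoint_map")) predicted$t_end_h else predicted
  m <- if (inherits(measured, "endpoint_map")) measured$t_end_h else measured
  target <- pmin(dim(p), dim(m))
  pa <- if (all(dim(p) == target)) p else resample_map(p, target)
  ma <- if (all(dim(m) == target)) m else resample_map(m, target)
  ok <- is.finite(pa) & is.finite(ma)
  if (!any(ok)) stop("compare_endpoint_maps: no jointly defined coordinates")
  pv <- pa[ok]; mv <- ma[ok]
  if (max(pv) < min(mv) || max(mv) < min(pv))
    warning("compare_endpoint_maps: the two endpoint distributions have disjoint supports")
  corr <- if (stats::sd(pv) > 0 && stats::sd(mv) > 0)
    stats::cor(pv, mv) else NA_real_
  grid <- sort(unique(c(pv, mv)))
  Fp <- stats::ecdf(pv)(grid); Fm <- stats::ecdf(mv)(grid)
  brk <- seq(min(pv, mv), max(pv, mv), length.out = n_bins + 1L)
  if (brk[1L] == brk[n_bins + 1L]) brk <- brk[1L] + c(-0.5, 0.5) / n_bins * seq(0, n_bins)
  hp <- graphics::hist(pv, breaks = brk, plot = FALSE)
  hm <- graphics::hist(mv, breaks = brk, plot = FALSE)
  qs <- rbind(predicted = stats::quantile(pv, c(.05, .5, .95)),
              measured = stats::quantile(mv, c(.05, .5, .95)))
  structure(list(correlation = corr,
                 max_cdf_distance = max(abs(Fp - Fm)),
                 quantiles = qs,
                 histogram = data.frame(mid = hp$mids,
                                        predicted = hp$counts,
                                        measured = hm$counts),
                 aligned = list(predicted = pa, measured = ma),
                 median_abs_diff_h = stats::median(abs(pv - mv))),
            class = "endpoint_comparison")
}

#' @export
print.endpoint_comparison <- function(x, ...) {
  cat(sprintf("<endpoint_comparison> r = %.3f; max CDF distance = %.3f; median |dt| = %.3f h\n",
              x$correlation, x$max_cdf_distance, x$median_abs_diff_h))
  print(round(x$quantiles, 3))
  invisible(x)
}
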