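# Regression of local dried-product mass-transfer resistance Rp(L_dr) from a
# measured layer series: temporal smoothing, segment volume, sublimation
# rate, projected area, driving pressure.

#' Process trace for the resistance regression
#'
#' Chamber pressure and sublimation-front temperature versus time. The
#' front temperature is a single (spatially uniform) thermocouple trace;
#' both quantities are linearly interpolated to the scan times.
#'
#' @param t time, s.
#' @param T_i front temperature, K (scalar or vector along `t`).
#' @param P_c chamber pressure, Pa (scalar or vector along `t`; the
#'   regression context default is 5 Pa).
#' @return object of class `process_trace`.
#' @export
process_trace <- function(t, T_i, P_c = 5) {
  n <- length(t)
  if (n < 1L || any(diff(t) <= 0)) stop("t must be strictly increasing")
  T_i <- rep_len(T_i, n); P_c <- rep_len(P_c, n)
  structure(list(t = t, T_i = T_i, P_c = P_c), class = "process_trace")
}

trace_at <- function(trace, t) {
  list(T_i = stats::approx(trace$t, trace$T_i, t, rule = 2)$y,
       P_c = stats::approx(trace$t, trace$P_c, t, rule = 2)$y)
}

#' Temporal smoothing of the layer series
#'
#' Applies Savitzky-Golay smoothing (degree 3, window 15) to `L_ice` over
#' time at every coordinate, then rebuilds `r_p = r_vial - L_ice`. Values
#' are clamped to `[0, r_vial]` after smoothing.
#'
#' @param series a `layer_series` with at least `window` time points.
#' @param window,degree filter parameters (defaults 15, 3).
#' @return smoothed `layer_series`.
#' @export
smooth_thickness <- function(series, window = 15L, degree = 3L) {
  stopifnot(inherits(series, "layer_series"))
  nt <- length(series$t)
  if (nt < window)
    stop(sprintf("smooth_thickness: %d time points but the Savitzky-Golay window requires at least %d",
                 nt, window))
  n <- dim(series$L_ice)[2L]; m <- dim(series$L_ice)[3L]
  for (j in seq_len(m)) for (i in seq_len(n)) {
    s <- savitzky_golay(series$L_ice[, i, j], window, degree)
    series$L_ice[, i, j] <- pmin(pmax(s, 0), series$r_vial)
  }
  series$r_p <- series$r_vial - series$L_ice
  series$smoothed <- TRUE
  series
}

#' Sublimation rate from a segment-volume series
#'
#' `m_dot = -dV/dt * rho_ice * theta_dr`, with the time derivative taken by
#' the Savitzky-Golay first-derivative filter (same degree/window as the
#' smoothing). Rates are reported positive during sublimation; times where
#' the volume is flat or increasing (noise) are masked invalid rather than
#' returned negative.
#'
#' @param V volume series, m^3 (uniformly sampled).
#' @param dt sample spacing, s.
#' @param constants a [physical_constants()].
#' @param window,degree Savitzky-Golay parameters.
#' @return list with `m_dot` (kg/s, `NA` where masked) and `valid`.
#' @export
sublimation_rate <- function(V, dt, constants = physical_constants(),
                             window = 15L, degree = 3L) {
  dVdt <- savitzky_golay(V, window, degree, deriv = 1L, dt = dt)
  m_dot <- -dVdt * constants$rho_ice * constants$theta_dr
  # a derivative at the numerical-noise floor of the filter is not signal
  tol <- 1e-9 * max(abs(V)) / dt * constants$rho_ice * constants$theta_dr
  valid <- m_dot > tol
  m_dot[!valid] <- NA_real_
  list(m_dot = m_dot, valid = valid)
}

#' Regress per-coordinate resistance profiles
#'
#' The full per-(Phi, h) pipeline: smooth `L_ice` over time, convert to
#' segment volume, differentiate to a sublimation rate, compute the
#' projected area and the driving pressure from the front-temperature
#' trace, and form `R_p = A_p * (P_i - P_c) / m_dot` paired with the dried
#' thickness `L_dr = L_ice(t_1) - L_ice(t)`. Entries with non-positive
#' sublimation rate or vanishing driving pressure are masked.
#'
#' The initial thickness is taken from the first scan of the (smoothed)
#' series; with scans starting minutes into drying this is a documented
#' small bias.
#'
#' @param series a `layer_series` (raw; smoothing is applied here unless
#'   `series$smoothed` is set).
#' @param trace a [process_trace()].
#' @param geometry a [scan_geometry()].
#' @param constants a [physical_constants()].
#' @param window,degree Savitzky-Golay parameters.
#' @return object of class `rp_profile_field` (unbinned): list with `t`,
#'   arrays `L_dr`, `R_p`, `m_dot`, `valid` of dim `[n_t, n_phi, n_h]`,
#'   `L_ice0` matrix, `binned = FALSE`.
#' @export
resistance_profile <- function(series, trace, geometry,
                               constants = physical_constants(),
                               window = 15L, degree = 3L) {
  stopifnot(inherits(series, "layer_series"), inherits(trace, "process_trace"))
  L_raw <- series$L_ice
  if (!isTRUE(series$smoothed))
    series <- smooth_thickness(series, window, degree)
  nt <- length(series$t)
  n <- dim(series$L_ice)[2L]; m <- dim(series$L_ice)[3L]
  dt <- diff(series$t)
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
    stop("resistance_profile assumes a uniform scan cadence")
  dt <- dt[1L]
  env <- trace_at(trace, series$t)
  P_i <- vapor_pressure_ice(env$T_i, constants)
  drive <- P_i - env$P_c                      # Pa, per time point
  # a sub-mPa driving pressure is indistinguishable from equilibrium
  drive[drive <= 1e-3] <- 0
  L_dr <- array(NA_real_, c(nt, n, m))
  R_p <- array(NA_real_, c(nt, n, m))
  MD <- array(NA_real_, c(nt, n, m))
  valid <- array(FALSE, c(nt, n, m))
  L_ice0 <- matrix(series$L_ice[1L, , ], n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    r_p <- series$r_p[, i, j]
    V <- segment_volume(r_p, geometry)
    sr <- sublimation_rate(V, dt, constants, window, degree)
    A_p <- projected_area(r_p, geometry)
    ok <- sr$valid & drive > 0
    # dry-kink guard: the polynomial window must not straddle the moment
    # the coordinate runs out of ice, where the derivative is biased low
    # (and Rp correspondingly high)
    k_dry <- which(L_raw[, i, j] <= geometry$dr / 2)
    if (length(k_dry))
      ok[seq_len(nt) > k_dry[1L] - 1L - (window - 1L) %/% 2L] <- FALSE
    rp_val <- A_p * drive / sr$m_dot
    rp_val[!ok] <- NA_real_
    R_p[, i, j] <- rp_val
    MD[, i, j] <- sr$m_dot
    L_dr[, i, j] <- dried_thickness(L_ice0[i, j], series$L_ice[, i, j])
    valid[, i, j] <- ok & is.finite(rp_val) & rp_val > 0
  }
  if (!any(valid))
    stop("resistance_profile: every coordinate-time is masked (no sublimation signal or no driving pressure)")
  structure(list(t = series$t, L_dr = L_dr, R_p = R_p, m_dot = MD,
                 valid = valid, L_ice0 = L_ice0, binned = FALSE,
                 geometry = geometry),
            class = "rp_profile_field")
}

#' Bin resistance profiles over dried thickness
#'
#' Bins each coordinate's `(L_dr, R_p)` points into `n_bins` equal bins
#' over `range` (default 38 bins over 0-2.5 mm) and reports the per-bin
#' median and count. The right edge of the last bin is inclusive; points
#' outside the range are dropped. Empty bins carry `NA` with count 0.
#'
#' @param field an unbinned `rp_profile_field` from [resistance_profile()].
#' @param n_bins number of bins (default 38).
#' @param range length-2 dried-thickness range in m (default `c(0, 2.5e-3)`).
#' @return object of class `rp_profile_field` with `binned = TRUE`: arrays
#'   `R_p` (per-bin median) and `count` of dim `[n_bins, n_phi, n_h]`,
#'   `bin_edges`, `bin_centers`.
#' @export
bin_profiles <- function(field, n_bins = 38L, range = c(0, 2.5e-3)) {
  stopifnot(inherits(field, "rp_profile_field"), !isTRUE(field$binned))
  edges <- seq(range[1L], range[2L], length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  n <- dim(field$R_p)[2L]; m <- dim(field$R_p)[3L]
  med <- array(NA_real_, c(n_bins, n, m))
  cnt <- array(0L, c(n_bins, n, m))
  width <- diff(range) / n_bins
  for (j in seq_len(m)) for (i in seq_len(n)) {
    ok <- field$valid[, i, j]
    if (!any(ok)) next
    ld <- field$L_dr[ok, i, j]; rp <- field$R_p[ok, i, j]
    b <- floor((ld - range[1L]) / width) + 1L
    b[ld >= range[2L] - 1e-15 & ld <= range[2L] + 1e-15] <- n_bins  # right edge inclusive
    keep <- b >= 1L & b <= n_bins
    b <- b[keep]; rp <- rp[keep]
    for (bb in unique(b)) {
      sel <- b == bb
      med[bb, i, j] <- stats::median(rp[sel])
      cnt[bb, i, j] <- sum(sel)
    }
  }
  structure(list(bin_edges = edges, bin_centers = centers, R_p = med,
                 count = cnt, L_ice0 = field$L_ice0, binned = TRUE,
                 geometry = field$geometry),
            class = "rp_profile_field")
}

#' Pool and re-bin a profile field onto a coarser (Phi, h) grid
#'
#' Spatial binning for resistance profiles: the raw `(L_dr, R_p)` points of
#' each block of coordinates are pooled, then binned as in
#' [bin_profiles()]. Used to coarsen the measured field to the simulation
#' grid.
#'
#' @param field an unbinned `rp_profile_field`.
#' @param factors integer pair `(f_phi, f_h)` dividing the grid dims.
#' @param geometry_out [scan_geometry()] of the coarse grid (for metadata).
#' @inheritParams bin_profiles
#' @return binned `rp_profile_field` on the coarse grid.
#' @export
pool_profiles <- function(field, factors, geometry_out = NULL,
                          n_bins = 38L, range = c(0, 2.5e-3)) {
  stopifnot(inherits(field, "rp_profile_field"), !isTRUE(field$binned))
  f <- as.integer(factors)
  n <- dim(field$R_p)[2L]; m <- dim(field$R_p)[3L]
  if (n %% f[1L] != 0L || m %% f[2L] != 0L)
    stop("factors must divide the (n_phi, n_h) grid")
  n2 <- n %/% f[1L]; m2 <- m %/% f[2L]
  edges <- seq(range[1L], range[2L], length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  width <- diff(range) / n_bins
  med <- array(NA_real_, c(n_bins, n2, m2))
  cnt <- array(0L, c(n_bins, n2, m2))
  for (J in seq_len(m2)) for (I in seq_len(n2)) {
    ii <- ((I - 1L) * f[1L] + 1L):(I * f[1L])
    jj <- ((J - 1L) * f[2L] + 1L):(J * f[2L])
    ok <- field$valid[, ii, jj]
    ld <- field$L_dr[, ii, jj][ok]
    rp <- field$R_p[, ii, jj][ok]
    if (!length(ld)) next
    b <- floor((ld - range[1L]) / width) + 1L
    b[abs(ld - range[2L]) <= 1e-15] <- n_bins
    keep <- b >= 1L & b <= n_bins
    b <- b[keep]; rp <- rp[keep]
    for (bb in unique(b)) {
      sel <- b == bb
      med[bb, I, J] <- stats::median(rp[sel])
      cnt[bb, I, J] <- sum(sel)
    }
  }
  structure(list(bin_edges = edges, bin_centers = centers, R_p = med,
                 count = cnt,
                 L_ice0 = spatial_bin(field$L_ice0, f),
                 binned = TRUE, geometry = geometry_out),
            class = "rp_profile_field")
}

#' @export
print.rp_profile_field <- function(x, ...) {
  if (isTRUE(x$binned)) {
    cat(sprintf("<rp_profile_field, binned> %d bins x %d x %d coordinates; %.0f%% bins populated\n",
                dim(x$R_p)[1L], dim(x$R_p)[2L], dim(x$R_p)[3L],
                100 * mean(x$count > 0)))
  } else {
    cat(sprintf("<rp_profile_field> %d scans x %d x %d coordinates; %.0f%% entries valid\n",
                dim(x$R_p)[1L], dim(x$R_p)[2L], dim(x$R_p)[3L],
                100 * mean(x$valid)))
  }
  invisible(x)
}
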