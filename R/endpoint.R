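# Primary-drying endpoint prediction: time-stepping of the coupled vial-level
# heat balance and per-coordinate mass balance.

#' Simulation configuration
#'
#' Parameters of the endpoint simulation. Defaults follow the reference
#' process: chamber pressure 10 Pa, total power to the vial 1.2 W, 60 s time
#' step, 10x spatial binning in both azimuth and height, 12 h horizon.
#'
#' @param P_c chamber pressure, Pa.
#' @param P_tot total power delivered to the vial, W (0 allowed: no
#'   sublimation).
#' @param dt time step, s.
#' @param bin_phi,bin_h spatial binning factors applied to the measured
#'   fields before simulation (must divide the grid dimensions).
#' @param max_time simulation horizon, s.
#' @param rp_min floor applied to interpolated resistances, m/s (guards the
#'   mass flux against a profile passing through zero).
#' @param constants a [physical_constants()] object.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(P_c = 10, P_tot = 1.2, dt = 60,
                              bin_phi = 10L, bin_h = 10L,
                              max_time = 43200,
                              rp_min = 1,
                              constants = physical_constants()) {
  if (dt <= 0) stop("dt must be > 0")
  if (max_time <= 0) stop("max_time must be > 0")
  structure(list(P_c = P_c, P_tot = P_tot, dt = dt,
                 bin_phi = as.integer(bin_phi), bin_h = as.integer(bin_h),
                 max_time = max_time, rp_min = rp_min, constants = constants),
            class = "simulation_config")
}

#' Block-average spatial binning of a (Phi, h) field
#'
#' Reduces an `n_phi x n_h` matrix by integer factors along each dimension
#' using the block mean (used to coarsen thickness and endpoint fields
#' before simulation; resistance profiles are pooled separately by
#' [bin_profiles()] on the coarse grid).
#'
#' @param field numeric matrix.
#' @param factors integer pair `(f_phi, f_h)`; each must divide the
#'   corresponding dimension.
#' @return reduced matrix of dimension `dim(field) / factors`.
#' @export
spatial_bin <- function(field, factors) {
  f <- as.integer(factors)
  d <- dim(field)
  if (length(f) != 2L || any(f < 1L)) stop("factors must be two integers >= 1")
  if (any(d %% f != 0L))
    stop(sprintf("binning factors (%d, %d) must divide the field dimensions (%d, %d)",
                 f[1L], f[2L], d[1L], d[2L]))
  n1 <- d[1L] %/% f[1L]; n2 <- d[2L] %/% f[2L]
  a <- array(field, dim = c(f[1L], n1, f[2L], n2))
  out <- apply(a, c(2L, 4L), mean)
  dim(out) <- c(n1, n2)
  out
}

#' Resistance-profile interpolator
#'
#' Builds a callable `R_p(L_dr)` from binned profile points: a cubic spline
#' (natural boundary conditions) through the valid knots, clamped to the
#' nearest endpoint value outside the knot range. With a single valid point
#' the profile is constant; with none the coordinate is unusable.
#'
#' @param L_dr,R_p numeric vectors of knot positions (m) and values (m/s);
#'   non-finite pairs are dropped.
#' @return function mapping `L_dr` (m) to `R_p` (m/s).
#' @export
rp_interpolator <- function(L_dr, R_p) {
  ok <- is.finite(L_dr) & is.finite(R_p)
  L_dr <- L_dr[ok]; R_p <- R_p[ok]
  if (length(L_dr) == 0L)
    stop("rp_interpolator: no valid (L_dr, R_p) points")
  if (length(L_dr) == 1L) {
    val <- R_p
    return(function(x) rep(val, length(x)))
  }
  o <- order(L_dr)
  L_dr <- L_dr[o]; R_p <- R_p[o]
  f <- stats::splinefun(L_dr, R_p, method = "natural")
  lo <- L_dr[1L]; hi <- L_dr[length(L_dr)]
  function(x) f(pmin(pmax(x, lo), hi))
}

# Core front stepper -------------------------------------------------------
#
# Shared by predict_endpoints() (regressed profiles) and simulate_series()
# (ground-truth profiles). At each step: solve the vial-level heat balance
# for a global interface temperature, distribute the mass flux over active
# coordinates through their local resistances, accumulate sublimed volume,
# and invert it to a front radius. Converged coordinates stop contributing
# area and mass from the following step.
step_front <- function(rp_funs, L_ice0, config, constants, geometry,
                       rp_vial_fun = NULL, record = FALSE) {
  n <- geometry$n_phi; m <- geometry$n_h
  stopifnot(all(dim(L_ice0) == c(n, m)))
  if (is.null(rp_vial_fun)) {
    # default vial-level profile: pointwise median over coordinate profiles
    rp_vial_fun <- function(L) {
      stats::median(vapply(rp_funs, function(f) f(L), numeric(1)))
    }
  }
  r_vial <- geometry$r_vial
  r_p0 <- r_vial - L_ice0
  active <- L_ice0 > 0
  V_full <- segment_volume(r_p0, geometry)     # total ice volume per segment
  V <- matrix(0, n, m)
  r_p <- r_p0
  t_end <- matrix(NA_real_, n, m)
  t <- 0
  hist <- list()
  snapshots <- list(r_p); snap_times <- 0
  step <- 0L
  while (any(active) && t < config$max_time) {
    step <- step + 1L
    L_dr <- r_p - r_p0
    if (config$P_tot <= 0) {
      # no power: nothing sublimates, fields stay frozen
      hist[[step]] <- data.frame(t = t, T_i = NA_real_, P_i = NA_real_,
                                 dH_sub = NA_real_, A_p_vial = 0,
                                 R_p_vial = NA_real_, L_dr_vial = 0,
                                 m_dot = 0, power_ratio = NA_real_,
                                 capped = FALSE)
      t <- t + config$dt
      if (record) { snapshots[[length(snapshots) + 1L]] <- r_p
                    snap_times <- c(snap_times, t) }
      if (t >= config$max_time) break
      next
    }
    L_dr_vial <- mean(L_dr[active])
    R_p_vial <- max(rp_vial_fun(L_dr_vial), config$rp_min)
    A_p_vial <- sum(projected_area(r_p[active], geometry))
    # Endgame: once the active area is small, P_tot may exceed the maximum
    # sublimation power below the triple point. The interface then sits at
    # the sublimation limit and the surplus power goes elsewhere (glass,
    # radiation); cap T_i at the bracket top and flag the step.
    T_top <- 273.16
    P_top <- suppressWarnings(vapor_pressure_ice(T_top, constants))
    max_power <- A_p_vial * (P_top - config$P_c) / R_p_vial *
      latent_heat_sublimation(T_top, constants) / constants$M
    capped <- max_power <= config$P_tot
    if (capped) {
      hb <- list(T_i = T_top, P_i = P_top,
                 dH_sub = latent_heat_sublimation(T_top, constants))
    } else {
      hb <- solve_interface_temperature(config$P_tot, A_p_vial, R_p_vial,
                                        config$P_c, constants)
    }
    drive <- hb$P_i - config$P_c
    idx <- which(active)
    R_i <- vapply(idx, function(i) rp_funs[[i]](L_dr[i]), numeric(1))
    R_i <- pmax(R_i, config$rp_min)
    A_i <- projected_area(r_p[idx], geometry)
    m_dot <- pmax(A_i * drive / R_i, 0)
    dV <- m_dot * config$dt / (constants$theta_dr * constants$rho_ice)
    V_new <- V[idx] + dV
    done <- V_new >= V_full[idx] - 1e-30
    if (any(done)) {
      j <- idx[done]
      frac <- ifelse(dV[done] > 0,
                     (V_full[idx][done] - V[idx][done]) / dV[done], 1)
      t_end[j] <- t + pmin(pmax(frac, 0), 1) * config$dt
      V[j] <- V_full[j]
      r_p[j] <- r_vial
      active[j] <- FALSE
    }
    not_done <- idx[!done]
    if (length(not_done)) {
      V[not_done] <- V[idx][!done] + dV[!done]
      r_p[not_done] <- pmin(front_radius_from_volume(V[not_done],
                                                     r_p0[not_done], geometry),
                            r_vial)
    }
    power_used <- sum(m_dot) * hb$dH_sub / constants$M
    hist[[step]] <- data.frame(t = t, T_i = hb$T_i, P_i = hb$P_i,
                               dH_sub = hb$dH_sub, A_p_vial = A_p_vial,
                               R_p_vial = R_p_vial, L_dr_vial = L_dr_vial,
                               m_dot = sum(m_dot),
                               power_ratio = power_used / config$P_tot,
                               capped = capped)
    t <- t + config$dt
    if (record) { snapshots[[length(snapshots) + 1L]] <- r_p
                  snap_times <- c(snap_times, t) }
  }
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(t = numeric(0), T_i = numeric(0), P_i = numeric(0),
               dH_sub = numeric(0), A_p_vial = numeric(0),
               R_p_vial = numeric(0), L_dr_vial = numeric(0),
               m_dot = numeric(0), power_ratio = numeric(0),
               capped = logical(0))
  list(t_end = t_end, converged = !active & (r_vial - L_ice0) < r_vial,
       unconverged = active, history = history,
       V = V, V_full = V_full,
       snapshots = if (record) snapshots else NULL,
       snap_times = if (record) snap_times else NULL)
}

#' Predict the intra-vial primary-drying endpoint distribution
#'
#' Time-steps the coupled vial-level heat balance and per-coordinate mass
#' balance. At each step the global interface temperature follows from the
#' total sublimating area and the vial-level (median-profile) resistance at
#' the mean dried thickness of the still-active coordinates; each active
#' coordinate then sublimates through its own interpolated resistance, its
#' sublimed volume is accumulated and inverted to a front radius, and the
#' coordinate converges when its dried thickness reaches its initial frozen
#' thickness. Endpoint times are refined by linear interpolation within the
#' converging step.
#'
#' @param rp_field a binned `rp_profile_field` (see [bin_profiles()]), or a
#'   list-matrix/function accepted by [ground_truth()] for synthetic runs.
#' @param L_ice0 matrix `[n_phi, n_h]` of initial frozen thickness, m.
#' @param config a [simulation_config()].
#' @param geometry a [scan_geometry()] whose `(n_phi, n_h)` match `L_ice0`.
#' @return object of class `endpoint_map`: list with `t_end_h` (hours,
#'   matrix), `converged`, `unconverged`, `history` (per-step vial-level
#'   data.frame with `T_i`, `P_i`, `dH_sub`, `A_p_vial`, `R_p_vial`,
#'   `L_dr_vial`, `m_dot`, `power_ratio`).
#' @export
predict_endpoints <- function(rp_field, L_ice0, config = simulation_config(),
                              geometry) {
  if (inherits(rp_field, "rp_profile_field")) {
    if (!isTRUE(rp_field$binned))
      stop("predict_endpoints expects a binned profile field; call bin_profiles() first")
    funs <- profile_field_interpolators(rp_field)
    vial_fun <- median_profile_interpolator(rp_field)
  } else {
    funs <- as_rp_fun_field(rp_field, geometry)
    vial_fun <- NULL
  }
  sim <- step_front(funs, L_ice0, config, config$constants, geometry,
                    rp_vial_fun = vial_fun)
  structure(list(t_end_h = sim$t_end / 3600, converged = sim$converged,
                 unconverged = sim$unconverged, history = sim$history,
                 config = config),
            class = "endpoint_map")
}

# per-coordinate interpolators from a binned profile field
profile_field_interpolators <- function(field) {
  n <- dim(field$R_p)[2L]; m <- dim(field$R_p)[3L]
  centers <- field$bin_centers
  funs <- vector("list", n * m)
  dim(funs) <- c(n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    rp <- field$R_p[, i, j]
    cnt <- field$count[, i, j]
    ok <- is.finite(rp) & cnt > 0
    if (!any(ok))
      stop(sprintf("coordinate (%d, %d) has no usable resistance profile", i, j))
    funs[[i + (j - 1L) * n]] <- rp_interpolator(centers[ok], rp[ok])
  }
  funs
}

# vial-level profile: per-bin median over coordinates, then spline
median_profile_interpolator <- function(field) {
  nb <- dim(field$R_p)[1L]
  med <- numeric(nb); has <- logical(nb)
  for (b in seq_len(nb)) {
    v <- field$R_p[b, , ][field$count[b, , ] > 0]
    v <- v[is.finite(v)]
    has[b] <- length(v) > 0L
    med[b] <- if (has[b]) stats::median(v) else NA_real_
  }
  if (!any(has)) stop("median profile: no populated bins")
  rp_interpolator(field$bin_centers[has], med[has])
}

#' @export
print.endpoint_map <- function(x, ...) {
  q <- stats::quantile(x$t_end_h, c(.05, .5, .95), na.rm = TRUE)
  cat(sprintf("<endpoint_map> %d x %d coordinates; t_end 5/50/95%%: %.2f / %.2f / %.2f h; %d unconverged\n",
              nrow(x$t_end_h), ncol(x$t_end_h), q[1], q[2], q[3],
              sum(x$unconverged)))
  invisible(x)
}
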