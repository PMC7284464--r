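# Shared fixtures. The rendered-phantom chain (render -> extract -> regress)
# is the expensive part of the suite, so it is built lazily once per run and
# reused by the module and acceptance tests.

demo_geometry <- function() {
  scan_geometry(voxel_size = 1e-4, dims = c(248L, 248L, 40L),
                n_radial = 124L, n_phi = 16L, n_h = 10L,
                r_vial = 10.9e-3, h_vial = 4e-3, scan_interval = 50)
}

# a coarser geometry for cheap rendering tests
tiny_geometry <- function() {
  scan_geometry(voxel_size = 2e-4, dims = c(124L, 124L, 20L),
                n_radial = 62L, n_phi = 16L, n_h = 10L,
                r_vial = 10.9e-3, h_vial = 4e-3, scan_interval = 50)
}

demo_sim_config <- function(dt = 10) {
  simulation_config(P_c = 10, P_tot = 1.2, dt = dt, max_time = 7200)
}

# per-coordinate true profiles with the three canonical shapes laid out in
# azimuthal sectors: constant, linear-increasing, crack-like decreasing
mixed_rp_truth <- function(geometry) {
  n <- geometry$n_phi; m <- geometry$n_h
  funs <- vector("list", n * m)
  dim(funs) <- c(n, m)
  shape_of <- function(i) c("constant", "linear", "crack")[(i - 1L) %/%
                                                            ceiling(n / 3) + 1L]
  for (j in seq_len(m)) for (i in seq_len(n)) {
    funs[[i + (j - 1L) * n]] <- switch(shape_of(i),
      constant = function(L) rep(1e5, length(L)),
      linear = function(L) 6e4 + 4e7 * L,
      crack = function(L) 1.3e5 - 3e7 * L)
  }
  attr(funs, "shape_of") <- shape_of
  funs
}

.fixture_cache <- new.env(parent = emptyenv())

# forward-simulate, render and extract the demo vial once per (noise, rp) set
demo_chain <- function(noise_sd = 0, rp = c("constant", "mixed")) {
  rp <- match.arg(rp)
  key <- sprintf("chain_%s_%g", rp, noise_sd)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  geom <- demo_geometry()
  th0 <- thickness_field(geom, base = 2e-3, gradient_frac = 0.2,
                         eccentricity = 0.05)
  spec <- phantom_spec(seed = 42L, noise_sd = noise_sd, scan_interval = 50)
  profs <- if (rp == "constant")
    function(L) rep(1e5, length(L)) else mixed_rp_truth(geom)
  truth <- ground_truth(profs, th0, geom)
  sim <- simulate_series(spec, geom, truth, demo_sim_config())
  series <- extract_layer_series(sim$frames, geom)
  trace <- process_trace(sim$truth$T_i_trace$t, sim$truth$T_i_trace$T_i,
                         P_c = 10)
  prof <- resistance_profile(series, trace, geom)
  binned <- bin_profiles(prof)
  out <- list(geom = geom, th0 = th0, truth = sim$truth, frames = sim$frames,
              scan_times = sim$scan_times, series = series, trace = trace,
              prof = prof, binned = binned, rp_funs = as_rp_list(profs, geom))
  .fixture_cache[[key]] <- out
  out
}

as_rp_list <- function(profs, geometry) {
  if (is.function(profs)) {
    funs <- rep(list(profs), geometry$n_phi * geometry$n_h)
    dim(funs) <- c(geometry$n_phi, geometry$n_h)
    funs
  } else profs
}

# median absolute relative error of binned Rp vs the true profiles,
# excluding each coordinate's first/last 10% of realized L_dr range
binned_recovery_errors <- function(binned, rp_funs) {
  n <- dim(binned$R_p)[2L]; m <- dim(binned$R_p)[3L]
  errs <- c()
  for (j in seq_len(m)) for (i in seq_len(n)) {
    cnt <- binned$count[, i, j]; rp <- binned$R_p[, i, j]
    ok <- cnt > 0 & is.finite(rp)
    if (!any(ok)) next
    ctr <- binned$bin_centers
    rng <- range(ctr[ok])
    sel <- ok & ctr >= rng[1] + 0.1 * diff(rng) & ctr <= rng[2] - 0.1 * diff(rng)
    truth <- rp_funs[[i + (j - 1L) * n]](ctr[sel])
    errs <- c(errs, abs(rp[sel] - truth) / truth)
  }
  errs
}
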