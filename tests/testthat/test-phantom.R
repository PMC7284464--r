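# Synthetic phantom generator: rendering, determinism, conservation,
# defects, forward simulation.

test_that("thickness field constructors respect gradients, eccentricity and bounds", {
  g <- demo_geometry()
  th <- thickness_field(g, base = 2e-3)
  expect_true(all(th == 2e-3))
  th_g <- thickness_field(g, base = 2e-3, gradient_frac = 0.2)
  # bottom (h = 0 side) thicker than top by ~20% of base
  expect_gt(th_g[1, 1], th_g[1, 10])
  expect_equal(mean(th_g[, 1]) - mean(th_g[, 10]), 2e-3 * 0.2 * 0.9,
               tolerance = 1e-3)
  th_e <- thickness_field(g, base = 2e-3, eccentricity = 0.1)
  expect_equal(max(th_e) - min(th_e), 2 * 0.1 * 2e-3, tolerance = 1e-2)
  expect_error(thickness_field(g, base = 12e-3), "within")
})

test_that("uniform noise-free phantom renders and extracts at half-voxel accuracy", {
  g <- tiny_geometry()
  th <- thickness_field(g, base = 2e-3)
  fr <- make_annulus_frame(phantom_spec(seed = 1), g, th)
  cyl <- to_cylindrical(fr, g, fr$axis)
  ex <- extract_radii(segment_ice(cyl, g), g)
  expect_lt(max(abs(ex$L_ice - 2e-3)), g$voxel_size / 2 + 1e-12)
})

test_that("rendering is deterministic given spec and seed", {
  g <- tiny_geometry()
  th <- thickness_field(g, base = 2e-3)
  spec <- phantom_spec(seed = 9, noise_sd = 0.05)
  f1 <- make_annulus_frame(spec, g, th, frame_index = 3L)
  f2 <- make_annulus_frame(spec, g, th, frame_index = 3L)
  expect_identical(f1$data, f2$data)
  f3 <- make_annulus_frame(spec, g, th, frame_index = 4L)
  expect_false(identical(f1$data, f3$data))
})

test_that("rendered ice volume matches the analytic annulus within 1%", {
  g <- demo_geometry()   # 2 mm / 100 um = 20 voxels thick
  th <- thickness_field(g, base = 2e-3)
  spec <- phantom_spec(seed = 1, levels = c(air = 0, ice = 0.5, glass = 0))
  fr <- make_annulus_frame(spec, g, th)
  vox <- sum(fr$data) / 0.5 * g$voxel_size^3
  analytic <- pi * g$h_vial * (g$r_vial^2 - (g$r_vial - 2e-3)^2)
  expect_equal(vox, analytic, tolerance = 0.01)
})

test_that("a carved cavity appears as the L_ice / L_ice_prime difference", {
  g <- demo_geometry()
  th <- thickness_field(g, base = 2e-3)
  spec <- phantom_spec(seed = 1, defects = list(defect_cavity(
    phi_range = c(0.5, 1.5), h_range = c(1e-3, 3e-3),
    radial_offset = 0.5e-3, radial_extent = 0.30e-3)))
  fr <- make_annulus_frame(spec, g, th)
  cyl <- to_cylindrical(fr, g, fr$axis)
  mask <- segment_ice(cyl, g)
  ex <- extract_radii(mask, g)
  lp <- pmin(integrated_length(mask, g), ex$L_ice)
  diffs <- ex$L_ice - lp
  patch <- diffs[diffs > 1e-5]
  expect_gt(length(patch), 0)
  expect_lt(max(abs(patch - 0.30e-3)), g$voxel_size)
  # and the radiality verdict flags it
  expect_true(radiality_map(ex$L_ice, lp)$non_radial)
})

test_that("phantom validation rejects impossible thickness", {
  g <- tiny_geometry()
  th <- thickness_field(g, base = 2e-3)
  expect_error(make_annulus_frame(phantom_spec(), g, th * 10), "r_vial")
  expect_error(make_annulus_frame(phantom_spec(), g, th[1:4, ]), "dimensions")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("zero total power freezes the series", {
  g <- tiny_geometry()
  th <- thickness_field(g, base = 2e-3)
  truth <- ground_truth(function(L) rep(1e5, length(L)), th, g)
  cfg <- simulation_config(P_c = 10, P_tot = 0, dt = 50, max_time = 200)
  sim <- simulate_series(phantom_spec(seed = 2, scan_interval = 100), g,
                         truth, cfg, n_scans = 3L)
  expect_identical(sim$frames[[1]]$data, sim$frames[[2]]$data)
  expect_identical(sim$frames[[1]]$data, sim$frames[[3]]$data)
})

test_that("the simulated front advances monotonically outward", {
  ch <- demo_chain(0, "constant")
  snaps <- ch$truth$stepper$snapshots
  for (k in seq_len(length(snaps) - 1L)) {
    expect_true(all(snaps[[k + 1L]] - snaps[[k]] >= -1e-15))
  }
})

test_that("rendered ice volume tracks the stepper mass ledger within 2%", {
  ch <- demo_chain(0, "constant")
  g <- ch$geom
  r_p0 <- g$r_vial - ch$th0
  # analytic remaining volume from the recorded front positions
  for (k in c(2L, 8L, 15L)) {
    r_p_k <- spinlyo:::interp_front(ch$truth$stepper, ch$scan_times[k], r_p0)
    ledger <- sum(segment_volume(pmin(r_p_k, g$r_vial), g))
    # voxel counting on the rendered frame (subtract the glass signal)
    fr <- ch$frames[[k]]
    lev <- phantom_spec()$levels
    glass_only <- make_annulus_frame(
      phantom_spec(seed = 42L), g, matrix(0, g$n_phi, g$n_h))
    vox <- (sum(fr$data) - sum(glass_only$data)) / lev[["ice"]] *
      g$voxel_size^3
    expect_equal(vox, ledger, tolerance = 0.02)
  }
})
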