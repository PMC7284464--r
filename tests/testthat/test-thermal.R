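# Thermal-imaging verification: field of view, unwrapping, detection,
# distribution comparison.

test_that("the horizontal field of view follows 2 d_w tan(alpha/2)", {
  # reference parameters reproduce the documented 0.12 m at 2 significant figures
  expect_equal(signif(hfov(0.15, 45.1), 2), 0.12)
  expect_equal(hfov(0.15, 45.1), 2 * 0.15 * tan(45.1 / 2 * pi / 180),
               tolerance = 1e-12)
  expect_equal(hfov(0.30, 45.1), 2 * hfov(0.15, 45.1))  # linear in distance
  expect_lt(hfov(0.15, 0.01), 1e-4)                     # alpha -> 0
  # strictly increasing in both arguments
  expect_true(all(diff(hfov(seq(0.1, 0.5, 0.1), 45.1)) > 0))
  expect_true(all(diff(hfov(0.15, seq(10, 170, 20))) > 0))
  expect_error(hfov(0.15, 0), "alpha")
  expect_error(hfov(0.15, 181), "alpha")
  expect_error(hfov(0, 45), "d_w")
})

test_that("camera spec enforces rotation synchronisation", {
  cam <- thermal_camera_spec(rpm = 5, frames_per_rev = 12)
  expect_equal(cam$frame_rate, 1)
  expect_error(thermal_camera_spec(frames_per_rev = 2.5), "integer")
  expect_error(thermal_camera_spec(alpha = 200), "alpha")
  expect_error(thermal_camera_spec(d_w = -1), "d_w")
})

test_that("a constant endpoint map ramps every pixel on the same frame", {
  cam <- thermal_camera_spec(frames_per_rev = 12, rpm = 5)
  te <- matrix(0.5, 12, 6)     # hours
  mv <- make_thermal_movie(te, cam, plateau = -25, heater = 40)
  # first frame index where any pixel leaves the plateau, per pixel column
  rise_frame <- apply(mv$frames[, 3, ] > -24.9, 1, which.max)
  expect_true(all(rise_frame == rise_frame[1]))
})

test_that("unwrapping covers all azimuths once per revolution at period 60/rpm", {
  cam <- thermal_camera_spec(frames_per_rev = 12, rpm = 5)
  te <- matrix(seq(0.2, 0.75, length.out = 12 * 6), 12, 6)
  mv <- make_thermal_movie(te, cam)
  tr <- unwrap_movie(mv)
  expect_equal(tr$period, 12)                     # s per revolution
  # each azimuth sampled exactly once per revolution, uniformly
  expect_true(all(abs(apply(tr$time, 2, diff) - tr$period) < 1e-9))
  # strips tile the full circle: azimuth index j mod k
  expect_equal(dim(tr$temp)[2], 12L)
  # constant-temperature movie -> constant traces
  mvc <- make_thermal_movie(matrix(10, 12, 6), cam,
                            plateau = -25, heater = 40, duration = 3600)
  trc <- unwrap_movie(mvc)
  expect_true(all(abs(trc$temp - trc$temp[1, 1, 1]) < 1e-12))
})

test_that("endpoint detection finds a constructed change point and skips flat traces", {
  tt <- seq(0, 10800, by = 12)
  te <- 5400
  temp <- ifelse(tt < te, -25, pmin(-25 + 0.5 * (tt - te), 40))
  got <- detect_endpoint(temp, tt)
  expect_lte(abs(got - te), 12)            # within one sample
  expect_true(is.na(detect_endpoint(rep(-25, 100), seq_len(100) * 12)))
  # invariance to a constant offset
  expect_equal(detect_endpoint(temp + 7, tt), got)
  expect_error(detect_endpoint(temp[1:5], tt[1:5]), "at least 10")
})

test_that("a two-level endpoint map is recovered as a two-mode distribution", {
  cam <- thermal_camera_spec(frames_per_rev = 16, rpm = 5, noise_sd = 0.3)
  te <- matrix(0.4, 16, 8); te[9:16, ] <- 0.8
  mv <- make_thermal_movie(te, cam, seed = 3)
  det <- detect_endpoint_map(unwrap_movie(mv))
  expect_true(all(is.finite(det)))
  # detected values cluster around the two construction levels
  cl <- ifelse(abs(det - 0.4) < abs(det - 0.8), 0.4, 0.8)
  expect_true(all(abs(det - cl) * 3600 <= 2 * 12))
  expect_equal(as.integer(table(cl)), c(64L, 64L))
})

test_that("noisy detection stays within two sampling periods nearly everywhere", {
  cam_noisy <- thermal_camera_spec(frames_per_rev = 16, rpm = 5, noise_sd = 0.5)
  cam_clean <- thermal_camera_spec(frames_per_rev = 16, rpm = 5, noise_sd = 0)
  set.seed(5)
  te <- matrix(runif(16 * 10, 0.3, 0.9), 16, 10)
  det_n <- detect_endpoint_map(unwrap_movie(make_thermal_movie(te, cam_noisy,
                                                               seed = 5)))
  det_c <- detect_endpoint_map(unwrap_movie(make_thermal_movie(te, cam_clean)))
  # oracle: noiseless detection
  dd <- abs(det_n - det_c) * 3600
  expect_gte(mean(dd <= 2 * 12, na.rm = TRUE), 0.95)
})

test_that("endpoint-map comparison summarises agreement correctly", {
  set.seed(8)
  a <- matrix(runif(16 * 10, 1, 2.7), 16, 10)
  cmp_same <- compare_endpoint_maps(a, a)
  expect_equal(cmp_same$correlation, 1)
  expect_equal(cmp_same$max_cdf_distance, 0)
  expect_equal(cmp_same$median_abs_diff_h, 0)
  cmp_shift <- compare_endpoint_maps(a, a + 0.1)
  expect_equal(cmp_shift$correlation, 1)
  expect_equal(cmp_shift$median_abs_diff_h, 0.1, tolerance = 1e-12)
  expect_equal(unname(cmp_shift$quantiles["measured", "50%"] -
                        cmp_shift$quantiles["predicted", "50%"]), 0.1,
               tolerance = 1e-12)
  # different grids align to the coarser one
  b <- matrix(1.5, 8, 5)
  cmp_grid <- compare_endpoint_maps(a, b)
  expect_equal(dim(cmp_grid$aligned$predicted), c(8L, 5L))
})
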