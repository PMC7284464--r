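# Endpoint simulation: binning, interpolation, stepping, conservation.

test_that("spatial binning reduces dimensions by block means", {
  x <- matrix(5, 20, 10)
  b <- spatial_bin(x, c(10, 10))
  expect_equal(dim(b), c(2L, 1L))
  expect_true(all(b == 5))
  # checkerboard averages to the midpoint
  cb <- outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0, 2, 4))
  expect_true(all(spatial_bin(cb, c(2, 2)) == 3))
  # the reference full-scale reduction: 1600 x 1000 -> 160 x 100
  big <- matrix(1, 1600, 1000)
  expect_equal(dim(spatial_bin(big, c(10, 10))), c(160L, 100L))
  expect_error(spatial_bin(matrix(1, 7, 4), c(2, 2)), "divide")
})

test_that("the profile interpolator passes through knots and clamps outside", {
  ld <- seq(0, 2e-3, length.out = 10)
  rp <- 1e5 + 4e7 * ld
  f <- rp_interpolator(ld, rp)
  expect_equal(f(ld[4]), rp[4], tolerance = 1e-12)
  expect_equal(f(5e-3), rp[10])      # clamp beyond last knot
  expect_equal(f(-1e-3), rp[1])      # clamp below first knot
  # dense knots track a smooth function within 1% between knots
  g <- function(x) 1e5 * (1 + 0.5 * sin(x / 4e-4))
  knots <- seq(0, 2e-3, length.out = 40)
  fi <- rp_interpolator(knots, g(knots))
  mid <- (knots[-1] + knots[-40]) / 2
  expect_lt(max(abs(fi(mid) - g(mid)) / g(mid)), 0.01)
  expect_error(rp_interpolator(numeric(0), numeric(0)), "no valid")
  # single point falls back to a constant
  expect_equal(rp_interpolator(1e-3, 5e4)(c(0, 2e-3)), c(5e4, 5e4))
})

test_that("a uniform vial dries in the energy-limited closed-form time", {
  g <- demo_geometry()
  pc <- physical_constants()
  th <- thickness_field(g, base = 2e-3)
  cfg <- demo_sim_config()
  em <- predict_endpoints(function(L) rep(1e5, length(L)), th, cfg, g)
  expect_lt(diff(range(em$t_end_h)), 1e-9)    # all coordinates equal
  r_p0 <- g$r_vial - 2e-3
  m_ice <- pi * g$h_vial * (g$r_vial^2 - r_p0^2) * pc$rho_ice * pc$theta_dr
  T_bar <- mean(em$history$T_i[!em$history$capped])
  t_closed <- m_ice * latent_heat_sublimation(T_bar, pc) / (pc$M * cfg$P_tot)
  expect_equal(em$t_end_h[1, 1] * 3600, t_closed, tolerance = 0.05)
})

test_that("halving the time step moves endpoints by less than 2%", {
  g <- demo_geometry()
  th <- thickness_field(g, base = 2e-3, gradient_frac = 0.2)
  em1 <- predict_endpoints(function(L) rep(1e5, length(L)), th,
                           demo_sim_config(dt = 20), g)
  em2 <- predict_endpoints(function(L) rep(1e5, length(L)), th,
                           demo_sim_config(dt = 10), g)
  expect_lt(max(abs(em2$t_end_h - em1$t_end_h) / em1$t_end_h), 0.02)
})

test_that("mass and energy ledgers close during the simulation", {
  g <- demo_geometry()
  pc <- physical_constants()
  th <- thickness_field(g, base = 2e-3, gradient_frac = 0.2,
                        eccentricity = 0.05)
  cfg <- demo_sim_config()
  sim <- step_front(as_rp_list(function(L) rep(1e5, length(L)), g), th,
                    cfg, pc, g)
  # per coordinate: accumulated sublimed volume equals the initial ice volume
  expect_equal(sim$V, sim$V_full, tolerance = 1e-9)
  expect_true(all(is.finite(sim$t_end)))
  expect_true(all(sim$t_end > 0))
  # step-wise energy: total m_dot * dH / M within 2% of P_tot (uncapped steps)
  h <- sim$history[!sim$history$capped, ]
  expect_true(all(abs(h$power_ratio - 1) < 0.02))
})

test_that("endpoints are monotone in thickness and resistance scaling", {
  g <- demo_geometry()
  cfg <- demo_sim_config()
  th <- thickness_field(g, base = 1.6e-3)
  th_b <- th; th_b[, 6:10] <- th_b[, 6:10] * 1.5
  em <- predict_endpoints(function(L) rep(1e5, length(L)), th_b, cfg, g)
  expect_true(all(em$t_end_h[, 6:10] > max(em$t_end_h[, 1:5])))
  # with a fixed total power the process is energy-limited: a uniform
  # multiplicative scaling of the resistance raises the interface
  # temperature but leaves the drying time nearly unchanged
  em_hi <- predict_endpoints(function(L) rep(2e5, length(L)), th, cfg, g)
  em_lo <- predict_endpoints(function(L) rep(1e5, length(L)), th, cfg, g)
  expect_gt(mean(em_hi$history$T_i, na.rm = TRUE),
            mean(em_lo$history$T_i, na.rm = TRUE))
  expect_lt(max(abs(em_hi$t_end_h - em_lo$t_end_h) / em_lo$t_end_h), 0.01)
})

test_that("predicted endpoints round-trip the phantom ground truth within 10%", {
  ch <- demo_chain(0, "constant")
  em <- predict_endpoints(ch$binned, ch$prof$L_ice0, demo_sim_config(),
                          ch$geom)
  rel <- abs(em$t_end_h - ch$truth$endpoints) / ch$truth$endpoints
  expect_lt(max(rel), 0.10)
  expect_false(any(em$unconverged))
})

test_that("endpoint history exposes the vial-level heat-balance state", {
  ch <- demo_chain(0, "constant")
  em <- predict_endpoints(ch$binned, ch$prof$L_ice0, demo_sim_config(),
                          ch$geom)
  h <- em$history
  expect_true(all(c("T_i", "P_i", "dH_sub", "A_p_vial", "R_p_vial",
                    "L_dr_vial", "m_dot", "power_ratio") %in% names(h)))
  uncapped <- !h$capped
  expect_true(all(h$T_i[uncapped] > 180 & h$T_i[uncapped] < 273.16))
  expect_true(all(h$L_dr_vial >= 0 &
                    h$L_dr_vial <= max(ch$prof$L_ice0) + 1e-12))
})
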