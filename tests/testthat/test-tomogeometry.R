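# Cylindrical conversion, segmentation and front extraction.

test_that("a solid centred cylinder converts to clean cylindrical occupancy", {
  g <- tiny_geometry()
  v <- g$voxel_size
  nx <- g$dims[1]; ny <- g$dims[2]; nz <- g$dims[3]
  R <- 6e-3
  xs <- (seq_len(nx) - 0.5) * v - nx * v / 2
  ys <- (seq_len(ny) - 0.5) * v - ny * v / 2
  r2 <- outer(xs^2, ys^2, `+`)
  slice <- (sqrt(r2) <= R) * 1.0
  vol <- array(rep(slice, nz), dim = c(nx, ny, nz))
  cyl <- to_cylindrical(vol, g, c(nx, ny) * v / 2)
  rc <- r_centers(g)
  expect_true(all(cyl$data[rc < R - v, , ] > 0.99))
  expect_true(all(cyl$data[rc > R + v & rc < (nx / 2 - 1) * v, , ] < 0.01,
                  na.rm = TRUE))
})

test_that("total ice volume is preserved by the coordinate conversion within 2%", {
  g <- demo_geometry()
  th <- thickness_field(g, base = 2e-3)
  spec <- phantom_spec(seed = 1, levels = c(air = 0, ice = 0.5, glass = 0))
  fr <- make_annulus_frame(spec, g, th)
  cart_vol <- sum(fr$data >= 0.25) * g$voxel_size^3
  cyl <- to_cylindrical(fr, g, fr$axis)
  mask <- cyl$data >= 0.25
  mask[is.na(mask)] <- FALSE
  rc <- r_centers(g)
  cyl_vol <- sum(rc[slice.index(mask, 1)[mask]]) * g$dr *
    (2 * pi / g$n_phi) * (g$h_vial / g$n_h)
  expect_equal(cyl_vol, cart_vol, tolerance = 0.02)
})

test_that("axis estimation hits the true axis on centred and offset phantoms", {
  g <- tiny_geometry()
  th <- thickness_field(g, base = 2e-3)
  fr <- make_annulus_frame(phantom_spec(seed = 1), g, th)
  expect_lt(max(abs(estimate_axis(fr, g) - fr$axis)), 0.5 * g$voxel_size)
  # keep the glass wall inside the footprint of the small test volume
  fr_off <- make_annulus_frame(phantom_spec(seed = 1, axis_offset = c(2, -1)),
                               g, th)
  expect_lt(max(abs(estimate_axis(fr_off, g) - fr_off$axis)), g$voxel_size)
  expect_error(estimate_axis(array(0, c(20, 20, 4)), g), "no contrast|annulus")
})

test_that("an off-centre phantom extracts correctly with the right axis", {
  g <- demo_geometry()
  th <- thickness_field(g, base = 2e-3)
  fr <- make_annulus_frame(phantom_spec(seed = 1, axis_offset = c(4, -3)),
                           g, th)
  cyl <- to_cylindrical(fr, g, estimate_axis(fr, g))
  ex <- extract_radii(segment_ice(cyl, g), g)
  expect_lte(max(abs(ex$L_ice - th)), g$voxel_size)
})

test_that("to_cylindrical rejects an axis outside the footprint and flags outside bins", {
  g <- tiny_geometry()
  vol <- array(0.5, dim = g$dims)
  expect_error(to_cylindrical(vol, g, c(-1e-3, 1e-3)), "outside")
  # axis near the corner: distant bins leave the footprint -> NA
  cyl <- to_cylindrical(vol, g, c(1e-3, 1e-3))
  expect_true(any(is.na(cyl$data)))
})

test_that("segmentation is idempotent on binary input and honours fixed thresholds", {
  g <- tiny_geometry()
  rc <- r_centers(g)
  data <- array(0, c(g$n_radial, g$n_phi, g$n_h))
  ann <- rc >= 8.9e-3 & rc < g$r_vial
  data[ann, , ] <- 1
  cyl <- structure(list(data = data, timestamp = 0, axis = c(0, 0)),
                   class = "cylindrical_frame")
  mask <- segment_ice(cyl, g)
  expect_identical(unname(mask[, 1, 1]), unname(ann))
  # fixed threshold above the ice level -> empty mask
  empty <- segment_ice(cyl, g, policy = list(method = "fixed", value = 2))
  expect_false(any(empty))
  expect_error(segment_ice(structure(list(data = array(0.5,
    c(g$n_radial, g$n_phi, g$n_h)), timestamp = 0, axis = c(0, 0)),
    class = "cylindrical_frame"), g), "degenerate")
})

test_that("extract_radii handles uniform annuli, empty columns and speck noise", {
  g <- demo_geometry()
  data <- array(FALSE, c(g$n_radial, g$n_phi, g$n_h))
  rc <- r_centers(g)
  data[rc >= 8.9e-3 & rc < g$r_vial, , ] <- TRUE
  ex <- extract_radii(data, g)
  expect_equal(ex$r_p, matrix(8.9e-3, g$n_phi, g$n_h), tolerance = 1e-12)
  expect_equal(ex$L_ice, matrix(2e-3, g$n_phi, g$n_h), tolerance = 1e-12)
  # empty column
  data2 <- data; data2[, 3, 4] <- FALSE
  ex2 <- extract_radii(data2, g)
  expect_equal(ex2$L_ice[3, 4], 0)
  expect_equal(ex2$r_p[3, 4], g$r_vial)
  # a stray single-bin speck near the axis must not set r_p
  data3 <- data; data3[5, 7, 7] <- TRUE
  ex3 <- extract_radii(data3, g)
  expect_equal(ex3$r_p[7, 7], 8.9e-3, tolerance = 1e-12)
})

test_that("integrated length counts classified bins and respects cavities", {
  g <- demo_geometry()   # dr = 100 um
  data <- array(FALSE, c(g$n_radial, g$n_phi, g$n_h))
  data[60:109, , ] <- TRUE            # 50 bins of 100 um = 5 mm
  expect_equal(integrated_length(data, g)[1, 1], 5e-3)
  data[80:82, 2, 2] <- FALSE          # 0.3 mm internal cavity
  lp <- integrated_length(data, g)
  ex <- extract_radii(data, g)
  expect_equal(ex$L_ice[2, 2] - lp[2, 2], 0.3e-3, tolerance = 1e-12)
  expect_equal(integrated_length(array(FALSE, dim(data)), g)[3, 3], 0)
})

test_that("radiality map computes relative differences and verdicts", {
  L <- matrix(2e-3, 4, 4); Lp <- L
  r0 <- radiality_map(L, Lp)
  expect_true(all(r0$rel_diff == 0))
  expect_false(r0$non_radial)
  Lp2 <- matrix(1.7e-3, 4, 4)
  expect_equal(radiality_map(L, Lp2)$rel_diff[1, 1], 0.15)
  L3 <- L; L3[1, 1] <- 0
  r3 <- radiality_map(L3, Lp)
  expect_true(is.na(r3$rel_diff[1, 1]))
})

test_that("layer-series extraction keeps the layer ordering invariant", {
  ch <- demo_chain(0, "constant")
  s <- ch$series
  expect_true(all(diff(s$t) > 0))
  expect_true(all(s$L_ice_prime >= -1e-15))
  expect_true(all(s$L_ice_prime <= s$L_ice + 1e-15))
  expect_true(all(s$L_ice <= s$r_vial + 1e-15))
})
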