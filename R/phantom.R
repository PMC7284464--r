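# Synthetic 4D-uCT phantom: a glass vial with an annular frozen layer of
# known local thickness, rendered as cartesian greyscale volumes with
# partial-volume boundary handling, optional defects and noise.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Describes a synthetic spin-frozen vial: greyscale attenuation levels for
#' the three material classes (air/dried product, ice, glass — the dried
#' layer is rendered indistinguishable from air, since its attenuation is
#' negligible), relative greyscale noise, defects, axis misalignment and the
#' scan cadence. One integer seed governs every stochastic draw.
#'
#' @param seed integer seed for all noise draws.
#' @param noise_sd relative greyscale noise (standard deviation as a
#'   fraction of the ice/air contrast), `>= 0`.
#' @param levels named numeric: attenuation of `air`, `ice`, `glass`.
#' @param defects list of defect records, see [defect_crack()],
#'   [defect_cavity()], [defect_gripper()].
#' @param axis_offset length-2 numeric, vial-axis offset from the volume
#'   centre in voxels (x, y).
#' @param wall_thickness glass wall thickness, m (rendering only).
#' @param scan_interval time between rendered frames, s.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         noise_sd = 0,
                         levels = c(air = 0, ice = 0.5, glass = 1),
                         defects = list(),
                         axis_offset = c(0, 0),
                         wall_thickness = 1e-3,
                         scan_interval = 176.11) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(all(c("air", "ice", "glass") %in% names(levels)))
  if (levels[["ice"]] <= levels[["air"]])
    stop("ice attenuation must exceed the air/dried level")
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 levels = levels, defects = defects,
                 axis_offset = axis_offset,
                 wall_thickness = wall_thickness,
                 scan_interval = scan_interval),
            class = "phantom_spec")
}

#' Initial frozen-layer thickness field
#'
#' Constructs an (n_phi x n_h) thickness field in metres. The base thickness
#' can be modulated by a linear top-to-bottom gradient (relative difference
#' between vial bottom and top, emulating insufficient spin velocity) and a
#' sinusoidal azimuthal eccentricity (vial spun off its true centre).
#'
#' @param geometry a [scan_geometry()].
#' @param base base thickness, m (default 2 mm).
#' @param gradient_frac relative bottom-minus-top thickness difference
#'   (e.g. `0.2` for 20%); bottom of vial (h = 0) is thicker.
#' @param eccentricity relative azimuthal amplitude (fraction of `base`).
#' @param ecc_phase azimuth (rad) of maximum thickness.
#' @return matrix `[n_phi, n_h]` of thickness, m.
#' @export
thickness_field <- function(geometry, base = 2e-3, gradient_frac = 0,
                            eccentricity = 0, ecc_phase = 0) {
  phi <- phi_centers(geometry)
  h <- h_centers(geometry)
  th <- outer(1 + eccentricity * cos(phi - ecc_phase),
              1 + gradient_frac * (0.5 - h / geometry$h_vial)) * base
  if (any(th < 0) || any(th > geometry$r_vial))
    stop("thickness field must lie within [0, r_vial]")
  th
}

#' Defect records for the phantom
#'
#' `defect_crack()` is a radial planar gap of given azimuthal width fully
#' penetrating the frozen layer; `defect_cavity()` is an internal void band
#' at a given radial offset from the inner ice surface; `defect_gripper()`
#' is a local thickness depression where a gripper shielded the vial wall
#' during spin-freezing.
#'
#' @param phi_center,phi_width azimuth centre and full width, rad.
#' @param h_range length-2 height interval, m.
#' @param phi_range length-2 azimuth interval, rad (within `[0, 2*pi)`).
#' @param radial_offset cavity offset from the local inner ice surface, m.
#' @param radial_extent cavity radial size, m (must stay inside the layer).
#' @param h_center,h_halfwidth gripper spot centre/half-height, m.
#' @param phi_halfwidth gripper spot azimuthal half-width, rad.
#' @param depth gripper thickness reduction, m.
#' @return a defect record (named list with a `kind` field).
#' @export
defect_crack <- function(phi_center, phi_width, h_range) {
  list(kind = "crack", phi_center = phi_center, phi_width = phi_width,
       h_range = h_range)
}

#' @rdname defect_crack
#' @export
defect_cavity <- function(phi_range, h_range, radial_offset, radial_extent) {
  if (radial_extent <= 0) stop("radial_extent must be > 0")
  list(kind = "cavity", phi_range = phi_range, h_range = h_range,
       radial_offset = radial_offset, radial_extent = radial_extent)
}

#' @rdname defect_crack
#' @export
defect_gripper <- function(phi_center, phi_halfwidth, h_center, h_halfwidth,
                           depth) {
  list(kind = "gripper_spot", phi_center = phi_center,
       phi_halfwidth = phi_halfwidth, h_center = h_center,
       h_halfwidth = h_halfwidth, depth = depth)
}

# smallest signed angular difference
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# apply gripper_spot defects to a thickness field
apply_thickness_defects <- function(th, spec, geometry) {
  phi <- phi_centers(geometry); h <- h_centers(geometry)
  for (d in spec$defects) {
    if (d$kind != "gripper_spot") next
    pm <- abs(ang_diff(phi, d$phi_center)) <= d$phi_halfwidth
    hm <- abs(h - d$h_center) <= d$h_halfwidth
    th[pm, hm] <- pmax(th[pm, hm] - d$depth, 0)
  }
  th
}

#' Render one cartesian greyscale volume of the vial phantom
#'
#' Renders a glass cylinder of inner radius `r_vial` containing an annular
#' ice layer whose local thickness is given per (Phi, h) coordinate. Voxels
#' straddling a material boundary receive an area-weighted greyscale
#' (partial-volume model), so sub-voxel interface positions are meaningful.
#' Cracks and cavities are carved out of the ice; gripper spots depress the
#' local thickness. Gaussian greyscale noise is added if requested;
#' rendering is deterministic given `spec$seed` and `frame_index`.
#'
#' @param spec a [phantom_spec()].
#' @param geometry a [scan_geometry()].
#' @param thickness numeric matrix `[n_phi, n_h]`, local frozen-layer
#'   thickness in m (see [thickness_field()]).
#' @param timestamp frame time, s.
#' @param frame_index integer, distinguishes the noise draw per frame.
#' @return object of class `volume_frame`: list with `data` (3D array
#'   `[nx, ny, nz]`), `timestamp`, `axis` (true axis position, m), `seed`.
#' @export
make_annulus_frame <- function(spec, geometry, thickness, timestamp = 0,
                               frame_index = 0L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(geometry, "scan_geometry"))
  if (!all(dim(thickness) == c(geometry$n_phi, geometry$n_h)))
    stop("thickness field dimensions must match (n_phi, n_h) of the geometry")
  if (any(thickness < 0) || any(thickness > geometry$r_vial))
    stop("thickness must lie within [0, r_vial]")
  th <- apply_thickness_defects(thickness, spec, geometry)
  v <- geometry$voxel_size
  nx <- geometry$dims[1L]; ny <- geometry$dims[2L]; nz <- geometry$dims[3L]
  axis <- c(nx, ny) / 2 * v + spec$axis_offset * v
  xs <- (seq_len(nx) - 0.5) * v - axis[1L]
  ys <- (seq_len(ny) - 0.5) * v - axis[2L]
  r <- sqrt(outer(xs^2, ys^2, `+`))
  phi <- atan2(rep(ys, each = nx), rep(xs, ny)) %% (2 * pi)
  dim(phi) <- c(nx, ny)
  phi_idx <- pmin(floor(phi / (2 * pi) * geometry$n_phi) + 1L, geometry$n_phi)
  lev <- spec$levels
  r_wall_out <- geometry$r_vial + spec$wall_thickness
  # glass coverage is z-independent
  f_glass <- pmin(pmax((r - geometry$r_vial) / v + 0.5, 0), 1) *
    pmin(pmax((r_wall_out - r) / v + 0.5, 0), 1)
  glass_slice <- f_glass * lev[["glass"]]
  vol <- array(0, dim = c(nx, ny, nz))
  dh <- geometry$h_vial / geometry$n_h
  cav <- Filter(function(d) d$kind == "cavity", spec$defects)
  crk <- Filter(function(d) d$kind == "crack", spec$defects)
  for (z in seq_len(nz)) {
    h <- (z - 0.5) * v
    slice <- glass_slice
    if (h <= geometry$h_vial) {
      h_idx <- pmin(floor(h / dh) + 1L, geometry$n_h)
      th_loc <- matrix(th[cbind(as.vector(phi_idx), h_idx)], nx, ny)
      r_inner <- geometry$r_vial - th_loc
      f_ice <- pmin(pmax((r - r_inner) / v + 0.5, 0), 1) *
        pmin(pmax((geometry$r_vial - r) / v + 0.5, 0), 1)
      f_ice[th_loc <= 0] <- 0
      for (d in cav) {
        if (h < d$h_range[1L] || h > d$h_range[2L]) next
        inmask <- phi >= d$phi_range[1L] & phi <= d$phi_range[2L] &
          r >= r_inner + d$radial_offset &
          r < r_inner + d$radial_offset + d$radial_extent
        f_ice[inmask] <- 0
      }
      for (d in crk) {
        if (h < d$h_range[1L] || h > d$h_range[2L]) next
        inmask <- abs(ang_diff(phi, d$phi_center)) <= d$phi_width / 2
        f_ice[inmask] <- 0
      }
      slice <- slice + f_ice * lev[["ice"]]
    }
    vol[, , z] <- slice
  }
  if (spec$noise_sd > 0) {
    contrast <- lev[["ice"]] - lev[["air"]]
    vol <- vol + with_seed(spec$seed + 7919L * as.integer(frame_index),
                           array(stats::rnorm(length(vol), 0,
                                              spec$noise_sd * contrast),
                                 dim = dim(vol)))
  }
  structure(list(data = vol, timestamp = timestamp, axis = axis,
                 seed = spec$seed, frame_index = as.integer(frame_index)),
            class = "volume_frame")
}

#' Ground truth container for phantom experiments
#'
#' Holds everything the downstream pipeline is supposed to recover: the true
#' per-coordinate resistance profiles, the true initial thickness field, and
#' (after forward simulation) the realized endpoints and the interface-
#' temperature trace.
#'
#' @param rp_profiles either a single function `R_p(L_dr)` in m/s applied to
#'   every coordinate, or a list-matrix (a list with `dim = c(n_phi, n_h)`)
#'   of such functions.
#' @param initial_thickness matrix `[n_phi, n_h]`, m.
#' @param geometry a [scan_geometry()].
#' @param T_i_trace optional data.frame `(t, T_i)` (s, K).
#' @param endpoints optional matrix of realized endpoints, hours.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(rp_profiles, initial_thickness, geometry,
                         T_i_trace = NULL, endpoints = NULL) {
  funs <- as_rp_fun_field(rp_profiles, geometry)
  if (!all(dim(initial_thickness) == c(geometry$n_phi, geometry$n_h)))
    stop("initial_thickness dims must be (n_phi, n_h)")
  structure(list(rp_funs = funs, initial_thickness = initial_thickness,
                 T_i_trace = T_i_trace, endpoints = endpoints),
            class = "ground_truth")
}

# normalize rp profile input to a list-matrix of functions
as_rp_fun_field <- function(rp_profiles, geometry) {
  n <- geometry$n_phi; m <- geometry$n_h
  if (is.function(rp_profiles)) {
    funs <- rep(list(rp_profiles), n * m)
    dim(funs) <- c(n, m)
    return(funs)
  }
  if (is.list(rp_profiles) && !is.null(dim(rp_profiles))) {
    if (!all(dim(rp_profiles) == c(n, m)))
      stop("rp_profiles list-matrix dims must be (n_phi, n_h)")
    stopifnot(all(vapply(rp_profiles, is.function, logical(1))))
    return(rp_profiles)
  }
  stop("rp_profiles must be a function or a list-matrix of functions")
}

#' Forward-simulate a scan series from ground truth
#'
#' Advances the sublimation front with the coupled heat/mass-balance stepper
#' (the same machinery as [predict_endpoints()]) using the *true* resistance
#' profiles, then renders a cartesian volume at each scan time. Returns the
#' frames together with the ground truth augmented by realized endpoints and
#' the interface-temperature trace.
#'
#' @param spec a [phantom_spec()].
#' @param geometry a [scan_geometry()].
#' @param truth a [ground_truth()].
#' @param config a [simulation_config()]; `config$dt` is the stepper
#'   resolution, `spec$scan_interval` the rendering cadence.
#' @param n_scans number of frames to render (default: until the last
#'   coordinate dries, plus one frame).
#' @return list with `frames` (list of `volume_frame`), `truth` (augmented
#'   [ground_truth()]), `scan_times` (s).
#' @export
simulate_series <- function(spec, geometry, truth, config = simulation_config(),
                            n_scans = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  sim <- step_front(truth$rp_funs, truth$initial_thickness, config,
                    config$constants, geometry, record = TRUE)
  if (is.null(n_scans)) {
    if (all(is.na(sim$t_end)))
      stop("simulate_series: nothing dries (P_tot = 0?); supply n_scans explicitly")
    n_scans <- ceiling(max(sim$t_end, na.rm = TRUE) / spec$scan_interval) + 1L
  }
  scan_times <- (seq_len(n_scans) - 1L) * spec$scan_interval
  r_vial <- geometry$r_vial
  r_p0 <- r_vial - truth$initial_thickness
  frames <- vector("list", n_scans)
  for (k in seq_len(n_scans)) {
    r_p_k <- interp_front(sim, scan_times[k], r_p0)
    L_k <- pmax(r_vial - r_p_k, 0)
    frames[[k]] <- make_annulus_frame(spec, geometry, L_k,
                                      timestamp = scan_times[k],
                                      frame_index = k)
  }
  truth$endpoints <- sim$t_end / 3600
  truth$T_i_trace <- data.frame(t = sim$history$t, T_i = sim$history$T_i,
                                P_c = config$P_c)
  truth$stepper <- sim
  list(frames = frames, truth = truth, scan_times = scan_times)
}

# linear interpolation of the recorded front radius snapshots at time t
interp_front <- function(sim, t, r_p0) {
  tt <- sim$snap_times
  if (t <= tt[1L]) return(sim$snapshots[[1L]])
  if (t >= tt[length(tt)]) return(sim$snapshots[[length(tt)]])
  i <- findInterval(t, tt)
  w <- (t - tt[i]) / (tt[i + 1L] - tt[i])
  (1 - w) * sim$snapshots[[i]] + w * sim$snapshots[[i + 1L]]
}
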