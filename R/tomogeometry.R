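# Cartesian-to-cylindrical conversion of reconstructed volumes, frozen-layer
# segmentation and per-(Phi, h) sublimation-front extraction.

#' Estimate the vial axis from a volume
#'
#' Detects the glass wall (the brightest attenuation class, found by two
#' nested Otsu thresholds: background vs material, then ice vs glass) and
#' returns the planar centroid of the wall annulus — for a full annulus the
#' centroid is the axis.
#'
#' @param frame a `volume_frame` (see [make_annulus_frame()]) or a 3D array.
#' @param geometry a [scan_geometry()].
#' @return numeric length-2, axis position (x, y) in metres from the volume
#'   corner.
#' @export
estimate_axis <- function(frame, geometry) {
  vol <- if (inherits(frame, "volume_frame")) frame$data else frame
  v <- geometry$voxel_size
  vals <- as.vector(vol)
  if (!any(is.finite(vals)) || diff(range(vals, finite = TRUE)) == 0)
    stop("estimate_axis: volume has no contrast; no wall annulus detected")
  t1 <- otsu_threshold(vals)
  hi <- vals[vals > t1]
  if (length(unique(round(hi, 10))) < 2L) {
    t2 <- t1
  } else {
    t2 <- otsu_threshold(hi)
  }
  mask <- vol > t2
  if (sum(mask) < 10L)
    stop("estimate_axis: no wall annulus detected")
  nx <- dim(vol)[1L]; ny <- dim(vol)[2L]
  ix <- slice.index(vol, 1L)[mask]
  iy <- slice.index(vol, 2L)[mask]
  c((mean(ix) - 0.5) * v, (mean(iy) - 0.5) * v)
}

# Otsu's bimodal histogram threshold (maximise between-class variance)
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("otsu_threshold: degenerate single-level histogram")
  brk <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, brk, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (brk[-1L] + brk[-(n_bins + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Convert a cartesian volume to the cylindrical data structure
#'
#' Resamples the greyscale volume onto an `(r, Phi, h)` grid by trilinear
#' interpolation at each bin-centre position relative to the supplied vial
#' axis. Bins whose sample point falls outside the cartesian footprint are
#' flagged `NA`.
#'
#' @param frame a `volume_frame` or 3D array.
#' @param geometry a [scan_geometry()].
#' @param axis_center planar axis position (x, y) in m; defaults to
#'   [estimate_axis()].
#' @return object of class `cylindrical_frame`: list with `data` (array
#'   `[n_radial, n_phi, n_h]`), `timestamp`, `axis`.
#' @export
to_cylindrical <- function(frame, geometry, axis_center = NULL) {
  vol <- if (inherits(frame, "volume_frame")) frame$data else frame
  timestamp <- if (inherits(frame, "volume_frame")) frame$timestamp else NA_real_
  v <- geometry$voxel_size
  nx <- dim(vol)[1L]; ny <- dim(vol)[2L]; nz <- dim(vol)[3L]
  if (is.null(axis_center)) axis_center <- estimate_axis(vol, geometry)
  if (axis_center[1L] < 0 || axis_center[1L] > nx * v ||
      axis_center[2L] < 0 || axis_center[2L] > ny * v)
    stop("to_cylindrical: axis outside the volume footprint")
  r <- r_centers(geometry); phi <- phi_centers(geometry); h <- h_centers(geometry)
  nr <- geometry$n_radial; np <- geometry$n_phi; nh <- geometry$n_h
  # sample positions in voxel index space (voxel centre i at (i - 0.5) * v)
  x <- outer(r, cos(phi)) + axis_center[1L]   # [nr, np]
  y <- outer(r, sin(phi)) + axis_center[2L]
  fx <- as.vector(x) / v + 0.5
  fy <- as.vector(y) / v + 0.5
  out <- array(NA_real_, dim = c(nr, np, nh))
  for (l in seq_len(nh)) {
    fz <- h[l] / v + 0.5
    out[, , l] <- trilinear_sample(vol, fx, fy, fz)
  }
  structure(list(data = out, timestamp = timestamp, axis = axis_center),
            class = "cylindrical_frame")
}

# trilinear interpolation at fractional voxel-centre coordinates (fx, fy
# vectors, fz scalar); outside the grid -> NA
trilinear_sample <- function(vol, fx, fy, fz) {
  nx <- dim(vol)[1L]; ny <- dim(vol)[2L]; nz <- dim(vol)[3L]
  x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
  wx <- fx - x0; wy <- fy - y0; wz <- fz - z0
  # clamp single-sided so points within half a voxel of the border still work
  ok <- fx >= 0.5 & fx <= nx + 0.5 & fy >= 0.5 & fy <= ny + 0.5 &
    fz >= 0.5 & fz <= nz + 0.5
  cx0 <- pmin(pmax(x0, 1L), nx); cx1 <- pmin(pmax(x0 + 1L, 1L), nx)
  cy0 <- pmin(pmax(y0, 1L), ny); cy1 <- pmin(pmax(y0 + 1L, 1L), ny)
  cz0 <- min(max(z0, 1L), nz); cz1 <- min(z0 + 1L, nz)
  sl0 <- vol[, , cz0]; sl1 <- vol[, , cz1]
  g <- function(sl, ix, iy) sl[cbind(ix, iy)]
  v00 <- (1 - wz) * g(sl0, cx0, cy0) + wz * g(sl1, cx0, cy0)
  v10 <- (1 - wz) * g(sl0, cx1, cy0) + wz * g(sl1, cx1, cy0)
  v01 <- (1 - wz) * g(sl0, cx0, cy1) + wz * g(sl1, cx0, cy1)
  v11 <- (1 - wz) * g(sl0, cx1, cy1) + wz * g(sl1, cx1, cy1)
  res <- (1 - wy) * ((1 - wx) * v00 + wx * v10) +
    wy * ((1 - wx) * v01 + wx * v11)
  res[!ok] <- NA_real_
  res
}

#' Segment the frozen layer in a cylindrical frame
#'
#' Thresholds the greyscale per bin. The default automatic policy is Otsu's
#' bimodal-histogram threshold computed over the interior (`r < r_vial`)
#' bins; a fixed threshold can be supplied instead. Glass is excluded by
#' masking all bins at or beyond the vial wall. Already-binary input is
#' returned unchanged (the Otsu threshold falls between the two levels).
#'
#' @param cyl a `cylindrical_frame`.
#' @param geometry a [scan_geometry()].
#' @param policy `list(method = "otsu")` (default) or
#'   `list(method = "fixed", value = <threshold>)`.
#' @return logical array `[n_radial, n_phi, n_h]`, `TRUE` for ice.
#' @export
segment_ice <- function(cyl, geometry, policy = list(method = "otsu")) {
  stopifnot(inherits(cyl, "cylindrical_frame"))
  interior <- r_centers(geometry) < geometry$r_vial
  vals <- cyl$data[interior, , , drop = FALSE]
  thr <- switch(policy$method,
    otsu = {
      fin <- vals[is.finite(vals)]
      if (length(unique(round(fin, 12))) < 2L)
        stop("segment_ice: degenerate single-level histogram under automatic policy")
      otsu_threshold(fin)
    },
    fixed = policy$value,
    stop("unknown threshold policy: ", policy$method))
  mask <- cyl$data >= thr
  mask[is.na(mask)] <- FALSE
  mask[!interior, , ] <- FALSE
  # glass partial-volume guard: bins within one radial bin of the wall pick
  # up bleed from the (much brighter) glass and can threshold as ice even
  # when the product there is gone; accept them only by continuity with the
  # bin just inside.
  shell <- which(interior & r_centers(geometry) >= geometry$r_vial - geometry$dr)
  for (k in shell) {
    if (k > 1L) mask[k, , ] <- mask[k, , ] & mask[k - 1L, , ]
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Extract front radius and frozen-layer thickness per (Phi, h)
#'
#' For every azimuth-height coordinate, `r_p` is the inner edge of the
#' innermost ice bin (the ice closest to the vial centre) and
#' `L_ice = r_vial - r_p`. Isolated radial runs shorter than `min_run` bins
#' are ignored when locating the front (speck filter), unless no longer run
#' exists. Coordinates with no ice get `r_p = r_vial`, `L_ice = 0`.
#'
#' @param mask logical array from [segment_ice()].
#' @param geometry a [scan_geometry()].
#' @param min_run minimum run length (bins) for a run to define the front.
#' @return list with matrices `r_p` and `L_ice` (`[n_phi, n_h]`, m).
#' @export
extract_radii <- function(mask, geometry, min_run = 2L) {
  stopifnot(all(dim(mask) == c(geometry$n_radial, geometry$n_phi, geometry$n_h)))
  dr <- geometry$dr
  n <- geometry$n_phi; m <- geometry$n_h
  r_p <- matrix(geometry$r_vial, n, m)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    col <- mask[, i, j]
    if (!any(col)) next
    runs <- rle(col)
    len <- runs$lengths; isice <- runs$values
    starts <- cumsum(c(1L, len[-length(len)]))
    cand <- which(isice & len >= min_run)
    if (!length(cand)) cand <- which(isice & len == max(len[isice]))
    first_bin <- starts[cand[1L]]
    r_p[i, j] <- min((first_bin - 1L) * dr, geometry$r_vial)
  }
  list(r_p = r_p, L_ice = geometry$r_vial - r_p)
}

#' Integrated frozen length per (Phi, h)
#'
#' Sums the radial lengths of all bins classified as ice: cavities inside
#' the layer are *not* counted, so `L_ice_prime <= L_ice` and their
#' difference measures internal voids (non-radial sublimation).
#'
#' @inheritParams extract_radii
#' @return matrix `[n_phi, n_h]` of integrated length, m.
#' @export
integrated_length <- function(mask, geometry) {
  stopifnot(all(dim(mask) == c(geometry$n_radial, geometry$n_phi, geometry$n_h)))
  apply(mask, c(2L, 3L), sum) * geometry$dr
}

#' Sublimation-direction diagnostic map
#'
#' Relative difference `(L_ice - L_ice_prime) / L_ice` per coordinate: zero
#' for a solid layer (purely radial sublimation), positive where internal
#' cavities exist. Coordinates with `L_ice = 0` are undefined (`NA`) and
#' excluded from the verdict.
#'
#' @param L_ice,L_ice_prime matrices from [extract_radii()] /
#'   [integrated_length()].
#' @param threshold per-coordinate relative difference regarded as
#'   non-radial (default 0.05).
#' @param area_fraction verdict flips to non-radial when more than this
#'   fraction of defined coordinates exceeds `threshold` (default 0.05).
#' @return list with `rel_diff` matrix, logical `non_radial` verdict, and
#'   `exceed_fraction`.
#' @export
radiality_map <- function(L_ice, L_ice_prime, threshold = 0.05,
                          area_fraction = 0.05) {
  stopifnot(all(dim(L_ice) == dim(L_ice_prime)))
  rel <- (L_ice - L_ice_prime) / L_ice
  rel[L_ice == 0] <- NA_real_
  defined <- !is.na(rel)
  frac <- if (any(defined)) mean(rel[defined] > threshold) else 0
  list(rel_diff = rel, non_radial = frac > area_fraction,
       exceed_fraction = frac)
}

#' Extract a layer series from a sequence of volumes
#'
#' Runs axis estimation (once, on the first frame), cylindrical conversion,
#' segmentation, and radius/length extraction on every frame, assembling
#' the per-scan `L_ice`, `L_ice_prime` and `r_p` fields.
#'
#' @param frames list of `volume_frame` objects (increasing timestamps).
#' @param geometry a [scan_geometry()].
#' @param axis_center optional fixed axis; default estimated from frame 1.
#' @param policy threshold policy for [segment_ice()].
#' @param min_run speck-filter run length for [extract_radii()].
#' @return object of class `layer_series`: list with `t` (s), arrays
#'   `L_ice`, `L_ice_prime`, `r_p` of dim `[n_t, n_phi, n_h]`, `r_vial`,
#'   `geometry`.
#' @export
extract_layer_series <- function(frames, geometry, axis_center = NULL,
                                 policy = list(method = "otsu"),
                                 min_run = 2L) {
  stopifnot(length(frames) >= 1L)
  if (is.null(axis_center)) axis_center <- estimate_axis(frames[[1L]], geometry)
  nt <- length(frames)
  n <- geometry$n_phi; m <- geometry$n_h
  L <- array(NA_real_, c(nt, n, m)); Lp <- L; RP <- L
  t <- numeric(nt)
  for (k in seq_len(nt)) {
    cyl <- to_cylindrical(frames[[k]], geometry, axis_center)
    mask <- segment_ice(cyl, geometry, policy)
    ex <- extract_radii(mask, geometry, min_run)
    L[k, , ] <- ex$L_ice
    RP[k, , ] <- ex$r_p
    Lp[k, , ] <- pmin(integrated_length(mask, geometry), ex$L_ice)
    t[k] <- frames[[k]]$timestamp
  }
  if (nt > 1L && any(diff(t) <= 0))
    stop("frame timestamps must be strictly increasing")
  structure(list(t = t, L_ice = L, L_ice_prime = Lp, r_p = RP,
                 r_vial = geometry$r_vial, geometry = geometry,
                 axis = axis_center),
            class = "layer_series")
}

#' @export
print.layer_series <- function(x, ...) {
  cat(sprintf("<layer_series> %d scans, %d x %d coordinates, t in [%.0f, %.0f] s\n",
              length(x$t), dim(x$L_ice)[2L], dim(x$L_ice)[3L],
              min(x$t), max(x$t)))
  invisible(x)
}
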