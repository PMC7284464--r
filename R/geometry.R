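#' Scan and vial geometry
#'
#' Describes one micro-CT acquisition: the cartesian voxel grid of the
#' reconstructed volume and the cylindrical segmentation used for analysis.
#' Defaults follow the reference acquisition (30 um voxels, 1300^3 volume,
#' 650 radial x 1600 azimuthal x 1300 height segmentations, 10R vial with
#' inner wall radius 10.9 mm and 32 mm product height); tests and the demo
#' pipeline use a reduced geometry.
#'
#' Conventions: indices are 1-based in R but bin 1 starts at coordinate 0;
#' azimuth bins cover `[0, 2*pi)` counterclockwise from the +x axis (bin
#' centres at `(j - 1/2) * 2*pi/n_phi`); height 0 is the vial bottom; radial
#' bins have width `voxel_size` by default, so bin k covers
#' `[(k-1)*dr, k*dr)`.
#'
#' @param voxel_size cartesian voxel edge length, m.
#' @param dims integer triple (nx, ny, nz) of the cartesian volume.
#' @param n_radial,n_phi,n_h cylindrical segmentation counts (r, Phi, h).
#' @param r_vial inner vial-wall radius, m.
#' @param h_vial height of the product-bearing vial section, m.
#' @param scan_interval time between successive 3D volumes, s.
#' @param dr radial bin width, m (default `voxel_size`).
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(voxel_size = 30e-6,
                          dims = c(1300L, 1300L, 1300L),
                          n_radial = 650L,
                          n_phi = 1600L,
                          n_h = 1000L,
                          r_vial = 10.9e-3,
                          h_vial = 32e-3,
                          scan_interval = 176.11,
                          dr = voxel_size) {
  stopifnot(length(dims) == 3L)
  dims <- as.integer(dims)
  if (!is.finite(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  if (any(dims < 1L)) stop("dims must be >= 1")
  if (n_radial < 1L || n_phi < 1L || n_h < 1L)
    stop("segmentation counts must be >= 1")
  if (r_vial > n_radial * dr)
    stop("r_vial exceeds the radial grid extent (n_radial * dr)")
  if (h_vial > dims[3L] * voxel_size + 1e-12)
    stop("h_vial exceeds the volume height (nz * voxel_size)")
  structure(list(voxel_size = voxel_size, dims = dims,
                 n_radial = as.integer(n_radial), n_phi = as.integer(n_phi),
                 n_h = as.integer(n_h),
                 r_vial = r_vial, h_vial = h_vial,
                 scan_interval = scan_interval, dr = dr),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %dx%dx%d voxels @ %.3g um; (r,phi,h) = (%d,%d,%d); r_vial %.3g mm, h_vial %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size * 1e6,
              x$n_radial, x$n_phi, x$n_h, x$r_vial * 1e3, x$h_vial * 1e3))
  invisible(x)
}

# bin-centre coordinate helpers --------------------------------------------

r_centers <- function(geometry) (seq_len(geometry$n_radial) - 0.5) * geometry$dr

phi_centers <- function(geometry)
  (seq_len(geometry$n_phi) - 0.5) * 2 * pi / geometry$n_phi

h_centers <- function(geometry)
  (seq_len(geometry$n_h) - 0.5) * geometry$h_vial / geometry$n_h

#' Volume of frozen product in one (Phi, h) segment
#'
#' Annular segment volume between the sublimation-front radius `r_p` and the
#' vial wall: `V = pi * h_vial / (n * m) * (r_vial^2 - r_p^2)` where `n` and
#' `m` are the azimuthal and height segmentation counts.
#'
#' @param r_p front radius, m (vectorised); must not exceed `r_vial`.
#' @param geometry a [scan_geometry()].
#' @return volume, m^3.
#' @export
segment_volume <- function(r_p, geometry) {
  if (any(r_p > geometry$r_vial + 1e-12, na.rm = TRUE))
    stop("segment_volume: r_p exceeds r_vial")
  pi * geometry$h_vial / (geometry$n_phi * geometry$n_h) *
    (geometry$r_vial^2 - r_p^2)
}

#' Invert the segment volume back to a front radius
#'
#' Exact inverse of the sublimed-volume/front-radius relation used by the
#' endpoint stepper: given the cumulative sublimed volume `V_subl` of a
#' segment whose front started at `r_p0`,
#' `r_p = sqrt(r_p0^2 + V_subl * n * m / (pi * h_vial))`.
#'
#' @param V_subl cumulative sublimed volume of the segment, m^3.
#' @param r_p0 initial front radius, m.
#' @param geometry a [scan_geometry()].
#' @return new front radius, m (not clamped to `r_vial`).
#' @export
front_radius_from_volume <- function(V_subl, r_p0, geometry) {
  sqrt(r_p0^2 + V_subl * geometry$n_phi * geometry$n_h /
         (pi * geometry$h_vial))
}

#' Projected sublimating area of one (Phi, h) segment
#'
#' Area of the segment face oriented toward the vial centre (the one-
#' dimensional radial model's sublimating surface):
#' `A_p = 2 * pi * h_vial * r_p / (n * m)`.
#'
#' @inheritParams segment_volume
#' @return area, m^2.
#' @export
projected_area <- function(r_p, geometry) {
  2 * pi * geometry$h_vial * r_p / (geometry$n_phi * geometry$n_h)
}

#' Dried-layer thickness
#'
#' `L_dr = L_ice0 - L_ice`: dried thickness is the initial frozen thickness
#' minus the current one. Small negative differences (smoothing overshoot)
#' are clamped to zero.
#'
#' @param L_ice0 initial frozen thickness, m.
#' @param L_ice current frozen thickness, m.
#' @return dried thickness, m.
#' @export
dried_thickness <- function(L_ice0, L_ice) {
  pmax(L_ice0 - L_ice, 0)
}
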