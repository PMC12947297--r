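#' Arc probe configuration
#'
#' Describes the rotated arc-shaped transducer probe: its radius, the
#' central angle subtended by the arc, and the number of point-like
#' elements distributed along it (the "ring" dimension of the data tensor).
#'
#' @param radius_mm Probe radius in mm (> 0).
#' @param central_angle_deg Arc extent in degrees, in (0, 180].
#' @param n_ring Number of elements along the arc (>= 1).
#'
#' @return An object of class `probe_config`.
#' @examples
#' probe_config(85, 90, 107)   # the hemispherical breast-imaging probe
#' @export
probe_config <- function(radius_mm, central_angle_deg, n_ring) {
  stopifnot(is.numeric(radius_mm), radius_mm > 0)
  if (!is.numeric(central_angle_deg) || central_angle_deg <= 0 ||
      central_angle_deg > 180) {
    stop("central_angle_deg must lie in (0, 180]")
  }
  n_ring <- as.integer(n_ring)
  if (is.na(n_ring) || n_ring < 1) stop("n_ring must be a positive count")
  structure(
    list(radius_mm = radius_mm, central_angle_deg = central_angle_deg,
         n_ring = n_ring),
    class = "probe_config"
  )
}

#' Scan configuration
#'
#' Bundles the probe with the tomographic acquisition parameters: number of
#' rotation views, temporal samples, sampling interval, and the constant
#' speed of sound of the coupling medium.  The total measurement count is
#' `M = n_time * n_views * n_ring`.
#'
#' @param probe A [probe_config()].
#' @param n_views Number of tomographic views Nv (>= 1).
#' @param n_time Number of temporal samples Nt (>= 2).
#' @param dt_us Sampling interval in microseconds (> 0).
#' @param c0_mps Speed of sound in m/s (> 0).
#' @param scan_type `"half"` (hemispherical aperture) or `"full"`
#'   (spherical aperture from a 180-degree arc).
#'
#' @return An object of class `scan_config`.
#' @examples
#' pr <- probe_config(85, 90, 107)
#' scan_config(pr, n_views = 320, n_time = 1280, dt_us = 0.1,
#'             c0_mps = 1509.15, scan_type = "half")
#' @export
scan_config <- function(probe, n_views, n_time, dt_us, c0_mps,
                        scan_type = c("half", "full")) {
  stopifnot(inherits(probe, "probe_config"))
  scan_type <- match.arg(scan_type)
  n_views <- as.integer(n_views); n_time <- as.integer(n_time)
  if (is.na(n_views) || n_views < 1) stop("n_views must be >= 1")
  if (is.na(n_time) || n_time < 2) stop("n_time must be >= 2")
  stopifnot(dt_us > 0, c0_mps > 0)
  structure(
    list(probe = probe, n_views = n_views, n_time = n_time,
         dt_us = dt_us, c0_mps = c0_mps, scan_type = scan_type),
    class = "scan_config"
  )
}

#' Speed of sound in mm/us
#' @param scan A [scan_config()].
#' @return Speed of sound converted to mm per microsecond.
#' @keywords internal
c0_mm_per_us <- function(scan) scan$c0_mps * 1e-3

#' Realize transducer positions on the spherical measurement segment
#'
#' Places `n_ring * n_views` idealized point transducers on the sphere of
#' the probe radius.  The aperture occupies the lower hemisphere `z <= 0`
#' with its rim in the plane `z = 0`.  Element `j` of the arc sits at polar
#' angle `(j + 0.5) * central_angle / n_ring` measured from the bottom pole
#' (-z axis), in the meridian half-plane at azimuth `2*pi*v / n_views` for
#' view `v`.  The flat transducer index is view-major, `q = v * n_ring + j`.
#'
#' Element areas are the spherical patch areas
#' `R^2 sin(theta) dtheta dphi`, used as quadrature weights by the standard
#' backprojection baseline.
#'
#' @param scan A [scan_config()].
#' @return An object of class `aperture_geometry` with fields
#'   `positions_mm` (Nq x 3 matrix, rows ordered by q),
#'   `inward_normals` (Nq x 3, unit vectors toward the sphere center),
#'   `element_area_mm2` (length Nq), and `ordering = "view-major"`.
#' @examples
#' geom <- build_aperture(scan_config(probe_config(85, 90, 4), 8, 64, 1, 1500))
#' nrow(geom$positions_mm)   # 32 transducers
#' @export
build_aperture <- function(scan) {
  stopifnot(inherits(scan, "scan_config"))
  pr <- scan$probe
  Nr <- pr$n_ring; Nv <- scan$n_views
  R <- pr$radius_mm
  dtheta <- pr$central_angle_deg * pi / 180 / Nr
  dphi <- 2 * pi / Nv
  # polar angle from the bottom pole, element centers offset by half a spacing
  theta <- (seq_len(Nr) - 0.5) * dtheta
  phi <- (seq_len(Nv) - 1) * dphi
  # view-major: q = v*Nr + j  ->  j varies fastest within a view
  th <- rep(theta, times = Nv)
  ph <- rep(phi, each = Nr)
  pos <- cbind(R * sin(th) * cos(ph),
               R * sin(th) * sin(ph),
               -R * cos(th))
  structure(
    list(positions_mm = pos,
         inward_normals = -pos / R,
         element_area_mm2 = R^2 * sin(th) * dtheta * dphi,
         ordering = "view-major"),
    class = "aperture_geometry"
  )
}

#' Check that a scan can record a grid without temporal truncation
#'
#' The interpolation-based imaging model assumes temporally untruncated
#' measurements: every spherical wavefront launched inside the volume must
#' arrive within the recording window, and the object support must lie
#' inside the convex hull of the hemispherical aperture (`z <= 0`,
#' `|r| < probe radius`).
#'
#' @param scan A [scan_config()].
#' @param grid A [volume_grid()].
#' @param values Optional volume array matching `grid`; when supplied, the
#'   convex-hull condition is only enforced for voxels with nonzero values
#'   (the object support).  Without it, every grid voxel must satisfy it.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_coverage <- function(scan, grid, values = NULL) {
  stopifnot(inherits(scan, "scan_config"), inherits(grid, "volume_grid"))
  cen <- voxel_centers(grid)
  if (!is.null(values)) {
    stopifnot(all(dim(values) == c(grid$nx, grid$ny, grid$nz)))
    keep <- which(values != 0)
    if (length(keep) == 0) return(invisible(TRUE))
    cen <- lapply(cen, function(a) a[keep])
  }
  geom <- build_aperture(scan)
  R <- scan$probe$radius_mm
  rad <- sqrt(cen$x^2 + cen$y^2 + cen$z^2)
  if (any(cen$z > 0) || any(rad >= R)) {
    stop("object outside convex hull of the measurement aperture")
  }
  # farthest voxel-to-transducer distance (voxels inside the sphere, so the
  # maximum is attained at the voxel farthest from each transducer; bound it
  # exactly by looping over transducers against the support extremes)
  maxd <- 0
  pos <- geom$positions_mm
  for (q in seq_len(nrow(pos))) {
    d <- sqrt((cen$x - pos[q, 1])^2 + (cen$y - pos[q, 2])^2 +
              (cen$z - pos[q, 3])^2)
    maxd <- max(maxd, max(d))
  }
  c0 <- c0_mm_per_us(scan)
  window_mm <- c0 * scan$n_time * scan$dt_us
  if (window_mm < maxd + c0 * scan$dt_us) {
    stop(sprintf(
      "temporal truncation: recording window %.1f mm < required %.1f mm",
      window_mm, maxd + c0 * scan$dt_us))
  }
  invisible(TRUE)
}

#' Write / read a scan configuration as YAML
#'
#' @param scan A [scan_config()].
#' @param path File path.
#' @return `write_scan_config` returns `path` invisibly;
#'   `read_scan_config` returns a [scan_config()].
#' @export
write_scan_config <- function(scan, path) {
  stopifnot(inherits(scan, "scan_config"))
  yaml::write_yaml(list(
    radius_mm = scan$probe$radius_mm,
    central_angle_deg = scan$probe$central_angle_deg,
    n_ring = scan$probe$n_ring,
    n_views = scan$n_views,
    n_time = scan$n_time,
    dt_us = scan$dt_us,
    c0_mps = scan$c0_mps,
    scan_type = scan$scan_type
  ), path)
  invisible(path)
}

#' @rdname write_scan_config
#' @export
read_scan_config <- function(path) {
  y <- yaml::read_yaml(path)
  scan_config(probe_config(y$radius_mm, y$central_angle_deg, y$n_ring),
              n_views = y$n_views, n_time = y$n_time, dt_us = y$dt_us,
              c0_mps = y$c0_mps, scan_type = y$scan_type)
}
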