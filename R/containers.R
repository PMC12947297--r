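#' Regular voxel grid
#'
#' Isotropic voxel lattice carrying the piecewise-linear expansion
#' coefficients of the initial pressure distribution.  `origin_mm` is the
#' physical center of voxel `(0, 0, 0)` (zero-based indexing); voxel
#' `(i, j, k)` sits at `origin_mm + voxel_mm * (i, j, k)`.
#'
#' @param nx,ny,nz Voxel counts along x, y, z (>= 1).
#' @param voxel_mm Isotropic voxel spacing in mm (> 0).
#' @param origin_mm Length-3 numeric, center of voxel (0,0,0) in mm.
#' @return An object of class `volume_grid`.
#' @examples
#' # grid centered on the x-y origin, spanning z in [-48, 0) mm
#' centered_grid(32, 32, 16, voxel_mm = 3)
#' @export
volume_grid <- function(nx, ny, nz, voxel_mm, origin_mm) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  stopifnot(nx >= 1, ny >= 1, nz >= 1, voxel_mm > 0,
            is.numeric(origin_mm), length(origin_mm) == 3)
  structure(
    list(nx = nx, ny = ny, nz = nz, voxel_mm = voxel_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "volume_grid"
  )
}

#' @describeIn volume_grid Grid centered on the z axis with its top voxel
#'   layer just below the aperture rim plane `z = 0` (the natural placement
#'   for a lower-hemisphere scan).
#' @export
centered_grid <- function(nx, ny, nz, voxel_mm) {
  volume_grid(nx, ny, nz, voxel_mm,
              origin_mm = c(-(nx - 1) / 2 * voxel_mm,
                            -(ny - 1) / 2 * voxel_mm,
                            -(nz - 0.5) * voxel_mm))
}

#' Voxel center coordinates
#' @param grid A [volume_grid()].
#' @return List of arrays `x`, `y`, `z`, each dim (nx, ny, nz), in mm.
#' @export
voxel_centers <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  xs <- grid$origin_mm[1] + grid$voxel_mm * (seq_len(grid$nx) - 1)
  ys <- grid$origin_mm[2] + grid$voxel_mm * (seq_len(grid$ny) - 1)
  zs <- grid$origin_mm[3] + grid$voxel_mm * (seq_len(grid$nz) - 1)
  d <- c(grid$nx, grid$ny, grid$nz)
  list(x = array(rep(xs, times = grid$ny * grid$nz), d),
       y = array(rep(rep(ys, each = grid$nx), times = grid$nz), d),
       z = array(rep(zs, each = grid$nx * grid$ny), d))
}

#' Discretized initial pressure volume
#'
#' @param grid A [volume_grid()].
#' @param values Numeric array dim `(nx, ny, nz)` of expansion coefficients
#'   (arbitrary pressure units); all values must be finite.
#' @return An object of class `object_volume`.
#' @export
object_volume <- function(grid, values) {
  stopifnot(inherits(grid, "volume_grid"))
  values <- as.array(values)
  if (!all(dim(values) == c(grid$nx, grid$ny, grid$nz))) {
    stop("values shape does not match grid")
  }
  if (!all(is.finite(values))) stop("non-finite voxel values")
  structure(list(grid = grid, values = values), class = "object_volume")
}

#' Measured pressure tensor
#'
#' Holds the measurement vector as a 3D tensor with axes (time, view, ring).
#' The canonical flat ordering enumerates sample `(w, v, j)` at position
#' `q * Nt + w` with view-major transducer index `q = v * Nr + j`; use
#' [as_measurement_vector()] to obtain it.
#'
#' @param scan A [scan_config()].
#' @param values Numeric array dim `(n_time, n_views, n_ring)`.
#' @return An object of class `pressure_data`.
#' @export
pressure_data <- function(scan, values) {
  stopifnot(inherits(scan, "scan_config"))
  values <- as.array(values)
  expected <- c(scan$n_time, scan$n_views, scan$probe$n_ring)
  if (!all(dim(values) == expected)) {
    stop(sprintf("values must have dim (Nt, Nv, Nr) = (%d, %d, %d)",
                 expected[1], expected[2], expected[3]))
  }
  structure(list(scan = scan, values = values), class = "pressure_data")
}

#' Flatten pressure data in the canonical measurement ordering
#'
#' @param p A [pressure_data()].
#' @return Numeric vector of length `Nt * Nv * Nr` where sample `(w, v, j)`
#'   occupies position `q * Nt + w + 1` with `q = v * Nr + j` (zero-based
#'   `w`, `v`, `j`).
#' @export
as_measurement_vector <- function(p) {
  stopifnot(inherits(p, "pressure_data"))
  as.vector(aperm(p$values, c(1, 3, 2)))
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(
    "scan_config: %s-scan, probe R=%g mm / %g deg / Nr=%d, Nv=%d, Nt=%d, dt=%g us, c0=%g m/s\n",
    x$scan_type, x$probe$radius_mm, x$probe$central_angle_deg,
    x$probe$n_ring, x$n_views, x$n_time, x$dt_us, x$c0_mps))
  invisible(x)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels at %g mm, origin (%g, %g, %g) mm\n",
              x$nx, x$ny, x$nz, x$voxel_mm,
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' @export
print.object_volume <- function(x, ...) {
  cat(sprintf("object_volume: %d x %d x %d, range [%.4g, %.4g]\n",
              x$grid$nx, x$grid$ny, x$grid$nz,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.pressure_data <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("pressure_data: (Nt, Nv, Nr) = (%d, %d, %d), range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}
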