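#' Discrete photoacoustic forward operator H
#'
#' Maps a discretized initial pressure volume to the pressure samples
#' recorded at every transducer: the composition of a spreading stage (each
#' voxel deposits its value, scaled by `h^3 / (4 pi c0^2 d tk)`, onto the
#' time bins bracketing its acoustic arrival `d / c0` via a triangle
#' interpolation kernel of half-width `tk = max(dt, h/c0)`) and a
#' central-difference time derivative.  With sampling no finer than the
#' voxel transit time (`c0 dt >= h`) this is exactly two-bin linear
#' interpolation; at finer sampling the widened kernel anti-aliases the
#' shell quadrature.  The map is linear in `f` and has an exact algebraic
#' transpose, [apply_adjoint()].
#'
#' @param f An [object_volume()].
#' @param geom An [aperture_geometry][build_aperture] matching `scan`.
#' @param scan A [scan_config()].
#' @return A [pressure_data()] with tensor dim `(Nt, Nv, Nr)`.
#' @seealso [apply_adjoint()], [analytic_sphere_signal()]
#' @export
apply_forward <- function(f, geom, scan) {
  stopifnot(inherits(f, "object_volume"), inherits(geom, "aperture_geometry"),
            inherits(scan, "scan_config"))
  validate_coverage(scan, f$grid, f$values)
  g <- f$grid
  p <- .cpp_forward(as.numeric(f$values),
                    c(g$nx, g$ny, g$nz), g$origin_mm, g$voxel_mm,
                    geom$positions_mm,
                    scan$n_time, scan$n_views, scan$probe$n_ring,
                    scan$dt_us, c0_mm_per_us(scan))
  pressure_data(scan, p)
}

#' Matched adjoint operator H-dagger (backprojection)
#'
#' Exact algebraic transpose of [apply_forward()]: the transposed
#' central-difference stencil followed by a per-voxel gather with the same
#' triangle weights and `h^3 / (4 pi c0^2 d dt)` factors.  Its global scale
#' is deliberately not normalized; the learned data filter absorbs any
#' fixed scale during training.
#'
#' @param p A [pressure_data()].
#' @param geom An [aperture_geometry][build_aperture].
#' @param scan A [scan_config()].
#' @param grid Target [volume_grid()].
#' @param voxel_subset Optional contiguous y-index range (1-based, e.g.
#'   `9:16`): only those y-slabs are computed (the rest of the returned
#'   volume is zero).  Slab values are bit-identical to the corresponding
#'   entries of the full adjoint.
#' @return An [object_volume()] on `grid`.
#' @export
apply_adjoint <- function(p, geom, scan, grid, voxel_subset = NULL) {
  stopifnot(inherits(p, "pressure_data"), inherits(geom, "aperture_geometry"),
            inherits(scan, "scan_config"), inherits(grid, "volume_grid"))
  if (is.null(voxel_subset)) {
    y0 <- 0L; y1 <- grid$ny
  } else {
    voxel_subset <- as.integer(voxel_subset)
    if (any(diff(voxel_subset) != 1L) || min(voxel_subset) < 1L ||
        max(voxel_subset) > grid$ny) {
      stop("voxel_subset must be a contiguous in-range y-index slab")
    }
    y0 <- min(voxel_subset) - 1L; y1 <- max(voxel_subset)
  }
  vol <- .cpp_adjoint(as.numeric(p$values),
                      c(grid$nx, grid$ny, grid$nz), grid$origin_mm,
                      grid$voxel_mm, geom$positions_mm,
                      scan$n_time, scan$n_views, scan$probe$n_ring,
                      scan$dt_us, c0_mm_per_us(scan), y0, y1)
  object_volume(grid, vol)
}

#' Closed-form N-wave signal of a uniform sphere
#'
#' Validation oracle for the forward model.  A homogeneous sphere of radius
#' `a` and initial pressure `A`, observed by a point transducer at distance
#' `d > a` from its center, produces the N-shaped wave
#' `p(t) = A (d - c0 t) / (2 d)` for `d - a < c0 t < d + a` and zero
#' elsewhere.
#'
#' @param center Length-3 numeric, sphere center in mm.
#' @param radius_a Sphere radius in mm.
#' @param amplitude Initial pressure amplitude.
#' @param rq Length-3 numeric, transducer position in mm.
#' @param scan A [scan_config()] fixing `Nt`, `dt_us`, `c0_mps`.
#' @return Numeric vector of length `Nt`: the signal sampled at
#'   `t = w * dt_us`, `w = 0 .. Nt-1`.
#' @export
analytic_sphere_signal <- function(center, radius_a, amplitude, rq, scan) {
  stopifnot(length(center) == 3, length(rq) == 3, radius_a > 0,
            inherits(scan, "scan_config"))
  d <- sqrt(sum((rq - center)^2))
  if (d <= radius_a) stop("transducer inside the sphere")
  c0 <- c0_mm_per_us(scan)
  t <- (seq_len(scan$n_time) - 1) * scan$dt_us
  ct <- c0 * t
  sig <- amplitude * (d - ct) / (2 * d)
  sig[ct <= d - radius_a | ct >= d + radius_a] <- 0
  sig
}

#' Voxelize a uniform sphere with partial-volume anti-aliasing
#'
#' Helper for building sphere phantoms on a grid: boundary voxels receive
#' the fraction of their volume inside the sphere (estimated on a
#' `ss^3` sub-voxel lattice), which suppresses staircase artifacts in
#' forward-model comparisons against [analytic_sphere_signal()].
#'
#' @param grid A [volume_grid()].
#' @param center Length-3 sphere center in mm.
#' @param radius_a Sphere radius in mm.
#' @param amplitude Interior amplitude.
#' @param ss Sub-sampling factor per axis for boundary voxels.
#' @return An [object_volume()].
#' @export
sphere_phantom <- function(grid, center, radius_a, amplitude = 1, ss = 4L) {
  cen <- voxel_centers(grid)
  h <- grid$voxel_mm
  d <- sqrt((cen$x - center[1])^2 + (cen$y - center[2])^2 +
            (cen$z - center[3])^2)
  vals <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  halfdiag <- h * sqrt(3) / 2
  vals[d <= radius_a - halfdiag] <- amplitude
  bnd <- which(abs(d - radius_a) < halfdiag)
  if (length(bnd) > 0) {
    off <- (seq_len(ss) - 0.5) / ss - 0.5   # sub-voxel offsets in voxel units
    sub <- as.matrix(expand.grid(off, off, off)) * h
    for (ii in bnd) {
      k <- (ii - 1) %/% (grid$nx * grid$ny)
      j <- ((ii - 1) %% (grid$nx * grid$ny)) %/% grid$nx
      i <- (ii - 1) %% grid$nx
      c0v <- grid$origin_mm + h * c(i, j, k)
      dd <- sqrt((sub[, 1] + c0v[1] - center[1])^2 +
                 (sub[, 2] + c0v[2] - center[2])^2 +
                 (sub[, 3] + c0v[3] - center[3])^2)
      vals[ii] <- amplitude * mean(dd <= radius_a)
    }
  }
  object_volume(grid, vals)
}
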