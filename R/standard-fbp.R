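#' Universal-backprojection data filtration
#'
#' The canonical analytic filtration used by full-scan FBP:
#' `b(t) = 2 p(t) - 2 t dp/dt`, discretized with a central difference and
#' zero extension at the time boundaries:
#' `b[q, w] = 2 p[q, w] - 2 (w dt) (p[q, w+1] - p[q, w-1]) / (2 dt)`.
#' Linear in `p`.
#'
#' @param p A [pressure_data()].
#' @return A filtered [pressure_data()].
#' @export
ubp_filter_data <- function(p) {
  stopifnot(inherits(p, "pressure_data"))
  x <- p$values
  Nt <- dim(x)[1]
  xp <- x[c(2:Nt, NA), , , drop = FALSE]; xp[is.na(xp)] <- 0
  xm <- x[c(NA, 1:(Nt - 1)), , , drop = FALSE]; xm[is.na(xm)] <- 0
  tw <- (seq_len(Nt) - 1) * p$scan$dt_us
  b <- 2 * x - 2 * array(tw, dim = dim(x)) * (xp - xm) / (2 * p$scan$dt_us)
  pressure_data(p$scan, b)
}

#' Standard FBP reconstruction (universal backprojection)
#'
#' Baseline analytic reconstruction: applies [ubp_filter_data()] and
#' backprojects with solid-angle-style weights
#' `w_qn = area_q |nhat_q . (r_n - r_q)| / d^2`, interpolating the filtered
#' trace linearly at the continuous arrival index `tau / dt`.  Each voxel
#' is normalized by its own total weight `sum_q w_qn`, so half- and
#' full-scan reconstructions share a common scale even though open
#' apertures have voxel-dependent angular coverage.  Applied to half-scan
#' data this exhibits the characteristic concentric arc artifacts near the
#' rim plane; applied to full-scan data it is quantitatively accurate.
#'
#' @param p A [pressure_data()].
#' @param geom An [aperture_geometry][build_aperture].
#' @param scan A [scan_config()].
#' @param grid Target [volume_grid()].
#' @return An [object_volume()].
#' @export
reconstruct_standard_fbp <- function(p, geom, scan, grid) {
  stopifnot(inherits(p, "pressure_data"), inherits(geom, "aperture_geometry"),
            inherits(scan, "scan_config"), inherits(grid, "volume_grid"))
  b <- ubp_filter_data(p)
  vol <- .cpp_backproject_ubp(as.numeric(b$values),
                              c(grid$nx, grid$ny, grid$nz), grid$origin_mm,
                              grid$voxel_mm, geom$positions_mm,
                              geom$inward_normals, geom$element_area_mm2,
                              scan$n_time, scan$n_views, scan$probe$n_ring,
                              scan$dt_us, c0_mm_per_us(scan))
  object_volume(grid, vol)
}
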