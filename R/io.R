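#' Raw float32 export of volumes and pressure tensors
#'
#' Writes the array as little-endian float32 in column-major (Fortran)
#' order next to a JSON sidecar (`<path>.json`) carrying the shape, axis
#' semantics and the full grid / scan configuration, so files are
#' self-describing and portable across languages.
#'
#' @param x An [object_volume()] or [pressure_data()].
#' @param path Output path for the binary payload.
#' @return `path`, invisibly.
#' @export
write_raw_f32 <- function(x, path) {
  if (inherits(x, "object_volume")) {
    meta <- list(kind = "volume", dtype = "float32", byte_order = "little",
                 order = "F", shape = dim(x$values),
                 axes = c("x", "y", "z"),
                 grid = x$grid[c("nx", "ny", "nz", "voxel_mm", "origin_mm")])
    vals <- x$values
  } else if (inherits(x, "pressure_data")) {
    s <- x$scan
    meta <- list(kind = "pressure", dtype = "float32",
                 byte_order = "little", order = "F", shape = dim(x$values),
                 axes = c("time", "view", "ring"),
                 scan = list(radius_mm = s$probe$radius_mm,
                             central_angle_deg = s$probe$central_angle_deg,
                             n_ring = s$probe$n_ring, n_views = s$n_views,
                             n_time = s$n_time, dt_us = s$dt_us,
                             c0_mps = s$c0_mps, scan_type = s$scan_type))
    vals <- x$values
  } else {
    stop("x must be an object_volume or pressure_data")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raw_f32
#' @export
read_raw_f32 <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  arr <- array(vals, dim = meta$shape)
  if (meta$kind == "volume") {
    g <- meta$grid
    object_volume(volume_grid(g$nx, g$ny, g$nz, g$voxel_mm, g$origin_mm), arr)
  } else {
    s <- meta$scan
    pressure_data(
      scan_config(probe_config(s$radius_mm, s$central_angle_deg, s$n_ring),
                  s$n_views, s$n_time, s$dt_us, s$c0_mps, s$scan_type),
      arr)
  }
}

#' Export transducer positions
#'
#' @param geom An [aperture_geometry][build_aperture].
#' @param path Output CSV path; columns `x_mm`, `y_mm`, `z_mm` in the
#'   view-major transducer order `q = v * n_ring + j`.
#' @return `path`, invisibly.
#' @export
write_aperture_positions <- function(geom, path) {
  stopifnot(inherits(geom, "aperture_geometry"))
  df <- as.data.frame(geom$positions_mm)
  names(df) <- c("x_mm", "y_mm", "z_mm")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
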