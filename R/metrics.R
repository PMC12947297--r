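#' Mean squared error between volumes
#'
#' @param a,b [object_volume()] objects on matching grids.
#' @return Mean of squared voxel differences over the full grid.
#' @export
compute_mse <- function(a, b) {
  stopifnot(inherits(a, "object_volume"), inherits(b, "object_volume"))
  if (!identical(dim(a$values), dim(b$values))) stop("grid mismatch")
  mean((a$values - b$values)^2)
}

# valid moving sum of a 3D array along one axis
.movsum_axis <- function(a, w, axis) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  x <- aperm(a, perm)
  d <- dim(x)
  cs <- apply(x, c(2, 3), cumsum)
  dim(cs) <- d
  zeros <- array(0, c(1, d[2], d[3]))
  cs0 <- array(0, c(d[1] + 1, d[2], d[3]))
  cs0[2:(d[1] + 1), , ] <- cs
  out <- cs0[(w + 1):(d[1] + 1), , , drop = FALSE] -
         cs0[1:(d[1] + 1 - w), , , drop = FALSE]
  aperm(out, order(perm))
}

# valid 3D box sum (w x w x w window)
.boxsum3 <- function(a, w) {
  .movsum_axis(.movsum_axis(.movsum_axis(a, w, 1), w, 2), w, 3)
}

#' Structural similarity index between volumes
#'
#' Mean local SSIM with a `window^3` uniform window (local moments over
#' fully interior windows only), constants `K1 = 0.01`, `K2 = 0.03`,
#' unbiased local (co)variances, and data range `max(ref) - min(ref)`.
#'
#' @param a An [object_volume()] under evaluation.
#' @param ref The reference [object_volume()]; must not be constant.
#' @param window Odd window side length (default 7).
#' @param K1,K2 Stability constants.
#' @return Scalar in `[-1, 1]`; exactly 1 when `a` equals `ref`.
#' @export
compute_ssim <- function(a, ref, window = 7L, K1 = 0.01, K2 = 0.03) {
  stopifnot(inherits(a, "object_volume"), inherits(ref, "object_volume"))
  if (!identical(dim(a$values), dim(ref$values))) stop("grid mismatch")
  L <- max(ref$values) - min(ref$values)
  if (L == 0) stop("constant reference volume: zero data range")
  if (any(dim(a$values) < window)) stop("volume smaller than SSIM window")
  x <- a$values; y <- ref$values
  n <- window^3
  mx <- .boxsum3(x, window) / n
  my <- .boxsum3(y, window) / n
  vx <- (.boxsum3(x^2, window) - n * mx^2) / (n - 1)
  vy <- (.boxsum3(y^2, window) - n * my^2) / (n - 1)
  cxy <- (.boxsum3(x * y, window) - n * mx * my) / (n - 1)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  ssim_map <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(ssim_map)
}

#' Extract a 1D line profile through a volume
#'
#' @param v An [object_volume()].
#' @param axis One of `"x"`, `"y"`, `"z"`: the axis along which the
#'   profile runs.
#' @param fixed Integer length-2 vector of 1-based indices fixing the two
#'   remaining axes, in grid axis order (e.g. for `axis = "z"`, the x and
#'   y indices).
#' @return Data frame with columns `coord_mm` (physical coordinate along
#'   the profile) and `value`.
#' @export
extract_line_profile <- function(v, axis = c("x", "y", "z"), fixed) {
  stopifnot(inherits(v, "object_volume"), length(fixed) == 2)
  axis <- match.arg(axis)
  g <- v$grid
  fixed <- as.integer(fixed)
  dims <- c(x = g$nx, y = g$ny, z = g$nz)
  others <- setdiff(names(dims), axis)
  if (fixed[1] < 1 || fixed[1] > dims[others[1]] ||
      fixed[2] < 1 || fixed[2] > dims[others[2]]) {
    stop("fixed indices out of range")
  }
  vals <- switch(axis,
                 x = v$values[, fixed[1], fixed[2]],
                 y = v$values[fixed[1], , fixed[2]],
                 z = v$values[fixed[1], fixed[2], ])
  ax_i <- match(axis, names(dims))
  coord <- g$origin_mm[ax_i] + g$voxel_mm * (seq_len(dims[axis]) - 1)
  data.frame(coord_mm = coord, value = vals)
}

#' Compare reconstruction methods against the truth
#'
#' Computes MSE and SSIM per method (and per sample, when lists of volumes
#' are supplied), together with per-method summary statistics
#' (median and interquartile range).
#'
#' @param truth An [object_volume()] or list of them.
#' @param reconstructions Named list; each element either an
#'   [object_volume()] or a list of them matching `truth` in length.
#' @return An object of class `recon_report`: a list with data frames
#'   `per_sample` and `summary`.
#' @export
compare_methods <- function(truth, reconstructions) {
  if (inherits(truth, "object_volume")) truth <- list(truth)
  if (is.null(names(reconstructions)) ||
      any(names(reconstructions) == "")) {
    stop("reconstructions must be a named list")
  }
  rows <- list()
  for (m in names(reconstructions)) {
    rec <- reconstructions[[m]]
    if (inherits(rec, "object_volume")) rec <- list(rec)
    if (length(rec) != length(truth)) stop("sample count mismatch for ", m)
    for (i in seq_along(rec)) {
      rows[[length(rows) + 1]] <- data.frame(
        method = m, sample = i,
        mse = compute_mse(rec[[i]], truth[[i]]),
        ssim = compute_ssim(rec[[i]], truth[[i]]))
    }
  }
  per_sample <- do.call(rbind, rows)
  if (any(!is.finite(per_sample$mse)) || any(!is.finite(per_sample$ssim))) {
    stop("non-finite metric encountered")
  }
  summ <- do.call(rbind, lapply(split(per_sample, per_sample$method),
    function(d) data.frame(
      method = d$method[1],
      median_mse = stats::median(d$mse),
      iqr_mse = stats::IQR(d$mse),
      median_ssim = stats::median(d$ssim),
      iqr_ssim = stats::IQR(d$ssim))))
  rownames(summ) <- NULL
  structure(list(per_sample = per_sample, summary = summ),
            class = "recon_report")
}

#' Write a reconstruction report to CSV and JSON
#'
#' @param report A [compare_methods()] result.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return The report, invisibly.
#' @export
write_recon_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "recon_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_sample, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_sample = report$per_sample,
                              summary = report$summary),
                         json_path, dataframe = "rows", digits = NA)
  }
  invisible(report)
}

#' @export
print.recon_report <- function(x, ...) {
  cat("recon_report\n")
  print(x$summary)
  invisible(x)
}
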