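#' Measurement noise specification
#'
#' The virtual-study noise model: i.i.d. zero-mean Gaussian samples with
#' standard deviation equal to a fixed fraction (default 1%) of the maximum
#' signal amplitude observed across the whole data ensemble (training,
#' validation and test together) -- not per-sample, so that every dataset
#' shares one physical noise level.
#'
#' @param fraction Noise standard deviation as a fraction of
#'   `reference_max` (>= 0).  Default 0.01.
#' @param seed Integer seed making the injection reproducible.
#' @param reference_max Maximum absolute signal amplitude over the intended
#'   ensemble (> 0).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(fraction = 0.01, seed = 1L, reference_max) {
  stopifnot(fraction >= 0, reference_max > 0)
  structure(list(fraction = fraction, seed = as.integer(seed),
                 reference_max = reference_max),
            class = "noise_spec")
}

#' Ensemble maximum amplitude
#'
#' @param datasets A list of [pressure_data()] objects (the ensemble over
#'   which the noise level is referenced).
#' @return The maximum absolute sample value across all datasets.
#' @export
ensemble_reference_max <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  max(vapply(datasets, function(p) max(abs(p$values)), numeric(1)))
}

#' Add i.i.d. Gaussian measurement noise
#'
#' @param p A [pressure_data()].
#' @param spec A [noise_spec()].
#' @return A [pressure_data()] with noise added; deterministic given
#'   `spec$seed`.
#' @export
add_gaussian_noise <- function(p, spec) {
  stopifnot(inherits(p, "pressure_data"), inherits(spec, "noise_spec"))
  if (spec$fraction == 0) return(p)
  sigma <- spec$fraction * spec$reference_max
  eps <- with_local_seed(spec$seed, {
    array(stats::rnorm(length(p$values), sd = sigma), dim = dim(p$values))
  })
  pressure_data(p$scan, p$values + eps)
}

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) saved <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Gaussian low-pass apodization of the time axis
#'
#' Convolves each temporal trace with a unit-area Gaussian kernel whose
#' impulse response has the requested half width at half maximum
#' (`sigma = hwhm / sqrt(2 log 2)`).  The kernel is truncated at +/- 4
#' sigma and renormalized so the DC gain is exactly 1; view and ring axes
#' are untouched.  Used to apodize the data filtering operation before
#' FBP-type reconstruction of noisy data (the virtual-study setting uses
#' `hwhm_us = 0.1177`).
#'
#' @param p A [pressure_data()].
#' @param hwhm_us Half width at half maximum of the impulse response, in
#'   microseconds (> 0).
#' @return A filtered [pressure_data()].
#' @export
gaussian_lowpass <- function(p, hwhm_us) {
  stopifnot(inherits(p, "pressure_data"))
  if (!is.numeric(hwhm_us) || hwhm_us <= 0) stop("hwhm_us must be > 0")
  k <- gaussian_lowpass_kernel(hwhm_us, p$scan$dt_us)
  d <- dim(p$values)
  x <- matrix(p$values, nrow = d[1])          # traces in columns
  half <- (length(k) - 1) / 2
  xp <- rbind(matrix(0, half, ncol(x)), x, matrix(0, half, ncol(x)))
  y <- apply(xp, 2, function(col) stats::filter(col, k, sides = 2))
  y <- y[(half + 1):(half + d[1]), , drop = FALSE]
  y[is.na(y)] <- 0
  pressure_data(p$scan, array(y, dim = d))
}

#' @describeIn gaussian_lowpass The discrete unit-sum kernel itself
#'   (odd length, centered).
#' @param dt_us Sampling interval in microseconds.
#' @export
gaussian_lowpass_kernel <- function(hwhm_us, dt_us) {
  sigma <- hwhm_us / sqrt(2 * log(2))
  half <- max(1L, ceiling(4 * sigma / dt_us))
  tt <- (-half:half) * dt_us
  k <- exp(-tt^2 / (2 * sigma^2))
  k / sum(k)
}

#' Measure the half width at half maximum of an impulse response
#'
#' Locates the peak of a sampled impulse response and the two half-maximum
#' crossings by linear sub-sample interpolation, returning half the
#' distance between them in time units.
#'
#' @param trace Numeric vector, the sampled impulse response (single peak).
#' @param dt_us Sampling interval in microseconds.
#' @return The HWHM in microseconds.
#' @export
measure_impulse_hwhm <- function(trace, dt_us) {
  stopifnot(length(trace) >= 3, dt_us > 0)
  ipk <- which.max(trace)
  half <- trace[ipk] / 2
  # left crossing
  il <- max(which(trace[1:ipk] < half))
  tl <- (il - 1) + (half - trace[il]) / (trace[il + 1] - trace[il])
  # right crossing
  ir <- ipk - 1 + min(which(trace[ipk:length(trace)] < half))
  tr <- (ir - 1) - (half - trace[ir]) / (trace[ir - 1] - trace[ir])
  (tr - tl) * dt_us / 2
}

#' Adapt a mismatched acquisition to a target scan shape
#'
#' Brings data recorded with a different sampling rate / ring count into
#' the tensor shape a pretrained filter expects: optional Gaussian
#' low-pass, temporal subsampling (every `subsample_factor`-th sample
#' starting at index 0), zero padding appended at the end of the time axis,
#' and symmetric zero padding of the ring axis (the extra slice goes at the
#' far end when the deficit is odd).
#'
#' @param p A [pressure_data()] from the source acquisition.
#' @param target A [scan_config()] describing the expected shape.
#' @param lowpass_hwhm_us Optional HWHM for a preliminary Gaussian
#'   low-pass; `NULL` skips filtering.
#' @param subsample_factor Integer temporal subsampling factor; must
#'   satisfy `source dt * factor = target dt`.
#' @return A [pressure_data()] with the target scan and shape.
#' @export
adapt_measurement <- function(p, target, lowpass_hwhm_us = NULL,
                              subsample_factor = 1L) {
  stopifnot(inherits(p, "pressure_data"), inherits(target, "scan_config"))
  subsample_factor <- as.integer(subsample_factor)
  src <- p$scan
  if (abs(src$dt_us * subsample_factor - target$dt_us) > 1e-9) {
    stop("incompatible sampling rates: source dt * factor != target dt")
  }
  if (src$n_views != target$n_views) stop("view counts differ")
  if (src$probe$n_ring > target$probe$n_ring) {
    stop("source ring count exceeds target")
  }
  if (!is.null(lowpass_hwhm_us)) p <- gaussian_lowpass(p, lowpass_hwhm_us)
  x <- p$values[seq(1, dim(p$values)[1], by = subsample_factor), , ,
                drop = FALSE]
  if (dim(x)[1] > target$n_time) stop("source time extent exceeds target")
  out <- array(0, dim = c(target$n_time, target$n_views,
                          target$probe$n_ring))
  deficit <- target$probe$n_ring - src$probe$n_ring
  lo <- deficit %/% 2                       # extra slice at the far end
  out[seq_len(dim(x)[1]), , lo + seq_len(src$probe$n_ring)] <- x
  pressure_data(target, out)
}
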