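#' Synthetic phantom specification
#'
#' Parameters of the seeded generator of 3D initial-pressure phantoms:
#' smooth Gaussian-profile ellipsoidal inclusions ("blobs") plus
#' random-walk tube structures ("vessels"), confined to a support ball
#' inside the hemispherical aperture's convex hull, with optional
#' exponential depth modulation emulating the decay of optical fluence with
#' depth.
#'
#' @param seed Integer seed; the phantom is a deterministic function of it.
#' @param n_blobs Length-2 integer range (inclusive) for the number of
#'   ellipsoidal inclusions.
#' @param n_vessels Length-2 integer range for the number of tube
#'   structures.
#' @param intensity_range `c(low, high)` nonnegative amplitude range
#'   (arbitrary pressure units) for individual structures; the final volume
#'   is capped at `high`.
#' @param background Baseline value outside structures (and everywhere
#'   outside the support).
#' @param depth_decay_mm Optional decay length of the `exp(-depth/decay)`
#'   modulation, with depth measured downward from the aperture rim plane
#'   `z = 0`; `NULL` disables it.
#' @param support_radius_mm Radius of the support ball (must stay inside
#'   the probe radius); structures are clipped to `|r| <= support_radius`
#'   and `z <= 0`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, n_blobs = c(2L, 5L),
                         n_vessels = c(1L, 3L),
                         intensity_range = c(0.4, 1),
                         background = 0, depth_decay_mm = NULL,
                         support_radius_mm = 60) {
  stopifnot(all(intensity_range >= 0), length(intensity_range) == 2,
            intensity_range[1] <= intensity_range[2],
            support_radius_mm > 0, length(n_blobs) == 2,
            length(n_vessels) == 2)
  structure(
    list(seed = as.integer(seed), n_blobs = as.integer(n_blobs),
         n_vessels = as.integer(n_vessels),
         intensity_range = intensity_range, background = background,
         depth_decay_mm = depth_decay_mm,
         support_radius_mm = support_radius_mm),
    class = "phantom_spec"
  )
}

#' Generate one synthetic initial-pressure phantom
#'
#' @param spec A [phantom_spec()].
#' @param grid A [volume_grid()]; the support ball must intersect it.
#' @return An [object_volume()], identical across calls with the same seed.
#' @export
generate_phantom <- function(spec, grid) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "volume_grid"))
  cen <- voxel_centers(grid)
  rad <- sqrt(cen$x^2 + cen$y^2 + cen$z^2)
  support <- rad <= spec$support_radius_mm & cen$z <= 0
  if (!any(support)) stop("empty support: grid does not meet the support ball")
  s <- with_local_seed(spec$seed, .generate_structures(spec, grid, cen, support))
  vals <- array(spec$background, dim = c(grid$nx, grid$ny, grid$nz))
  vals[support] <- pmin(spec$background + s[support],
                        spec$intensity_range[2])
  object_volume(grid, vals)
}

.generate_structures <- function(spec, grid, cen, support) {
  s <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  rs <- spec$support_radius_mm
  zmin <- min(cen$z[support]); zmax <- 0
  draw_center <- function() {
    repeat {
      ctr <- c(stats::runif(2, -0.7 * rs, 0.7 * rs),
               stats::runif(1, max(zmin * 0.9, -0.9 * rs), -0.1 * rs))
      if (sqrt(sum(ctr^2)) < 0.85 * rs) return(ctr)
    }
  }
  nb <- sample(spec$n_blobs[1]:spec$n_blobs[2], 1)
  for (b in seq_len(nb)) {
    ctr <- draw_center()
    semi <- stats::runif(3, 0.08, 0.22) * rs
    # random orientation via QR of a Gaussian matrix
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    amp <- stats::runif(1, spec$intensity_range[1], spec$intensity_range[2])
    dx <- cen$x - ctr[1]; dy <- cen$y - ctr[2]; dz <- cen$z - ctr[3]
    u1 <- (Q[1, 1] * dx + Q[2, 1] * dy + Q[3, 1] * dz) / semi[1]
    u2 <- (Q[1, 2] * dx + Q[2, 2] * dy + Q[3, 2] * dz) / semi[2]
    u3 <- (Q[1, 3] * dx + Q[2, 3] * dy + Q[3, 3] * dz) / semi[3]
    s <- s + amp * exp(-0.5 * (u1^2 + u2^2 + u3^2) * 4)
  }
  nv <- sample(spec$n_vessels[1]:spec$n_vessels[2], 1)
  h <- grid$voxel_mm
  for (vzz in seq_len(nv)) {
    pos <- draw_center()
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    radius <- stats::runif(1, 1, 3) * h
    amp <- stats::runif(1, spec$intensity_range[1], spec$intensity_range[2])
    n_steps <- 24L
    for (st in seq_len(n_steps)) {
      # splat a Gaussian tube cross-section at the current walk point
      d2 <- (cen$x - pos[1])^2 + (cen$y - pos[2])^2 + (cen$z - pos[3])^2
      near <- d2 < (3 * radius)^2
      s[near] <- pmax(s[near], amp * exp(-d2[near] / (2 * (radius / 1.5)^2)))
      dir <- dir + stats::rnorm(3, sd = 0.35)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir * h * 1.5
      if (sqrt(sum(pos^2)) > 0.85 * rs || pos[3] > -0.05 * rs) break
    }
  }
  if (!is.null(spec$depth_decay_mm)) {
    s <- s * exp(-pmax(0, -cen$z) / spec$depth_decay_mm)
  }
  s
}

#' Generate a deterministic ensemble of phantoms
#'
#' Phantom `i` uses seed `base_spec$seed + i - 1`, so ensembles are
#' reproducible and splits drawn from disjoint seed ranges never overlap.
#'
#' @param n Number of phantoms (>= 1).
#' @param base_spec A [phantom_spec()]; its seed anchors the ensemble.
#' @param grid A [volume_grid()].
#' @return List of `n` [object_volume()] objects.
#' @export
generate_ensemble <- function(n, base_spec, grid) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$seed <- base_spec$seed + i - 1L
    generate_phantom(sp, grid)
  })
}
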