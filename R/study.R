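#' Reference acquisition configurations
#'
#' The full-scale virtual-study acquisition: a rotated arc probe of radius
#' 85 mm with 107 elements over a 90-degree arc (hemispherical half-scan
#' aperture; about 0.84 degrees between adjacent elements), 320 tomographic
#' views, 1280 time samples at 10 MHz, and a reference speed of sound of
#' 1509.15 m/s.  The full-scan counterpart uses a 180-degree arc with 213
#' elements, forming a complete spherical aperture.
#'
#' @param scan_type `"half"` or `"full"`.
#' @return A [scan_config()].
#' @examples
#' reference_scan_config("half")
#' @export
reference_scan_config <- function(scan_type = c("half", "full")) {
  scan_type <- match.arg(scan_type)
  if (scan_type == "half") {
    scan_config(probe_config(85, 90, 107), n_views = 320, n_time = 1280,
                dt_us = 0.1, c0_mps = 1509.15, scan_type = "half")
  } else {
    scan_config(probe_config(85, 180, 213), n_views = 320, n_time = 1280,
                dt_us = 0.1, c0_mps = 1509.15, scan_type = "full")
  }
}

#' Reference reconstruction grid
#'
#' The full-scale object discretization: 340 x 340 x 170 voxels at 0.5 mm
#' (a 170 x 170 x 85 mm volume filling the lower hemisphere).
#'
#' @return A [volume_grid()].
#' @export
reference_grid <- function() {
  centered_grid(340, 340, 170, voxel_mm = 0.5)
}

#' Desk-scale virtual study conditions
#'
#' The package's default scaled-down virtual study, used throughout the
#' test suite and documentation.  All components keep the full-scale
#' acquisition's proportions (90-degree arc of radius 85 mm rotated over a
#' full turn; reference speed of sound) at sizes a single CPU handles in
#' minutes:
#' \itemize{
#'   \item half-scan: 8 ring elements, 16 views, 64 time samples at 2 us
#'     (the sampling interval keeps `c0 dt >= voxel`, so the forward model
#'     uses plain two-bin interpolation);
#'   \item full-scan reference: 16 elements over 180 degrees, same views
#'     and sampling;
#'   \item grid: 32 x 32 x 16 voxels at 3 mm (96 x 96 x 48 mm), inside the
#'     aperture's convex hull;
#'   \item phantoms: blob/vessel structures within a 42 mm support ball,
#'     depth-decay length 60 mm;
#'   \item filter: 3 levels, 4 base channels, bound to the (64, 16, 8)
#'     data shape;
#'   \item training: Adam, learning rate 1e-3, 25 epochs, slab fraction
#'     1/4, 12 training / 3 validation / 4 test phantoms.
#' }
#'
#' @param seed Integer seed anchoring phantom generation, network
#'   initialization and training stochasticity.
#' @return A list with elements `scan`, `geom`, `fullscan`, `fgeom`,
#'   `grid`, `phantom`, `net_config`, `train`, and the split sizes
#'   `n_train`, `n_val`, `n_test`.
#' @export
desk_study_conditions <- function(seed = 1L) {
  seed <- as.integer(seed)
  scan <- scan_config(probe_config(85, 90, 8), n_views = 16, n_time = 64,
                      dt_us = 2, c0_mps = 1509.15, scan_type = "half")
  fullscan <- scan_config(probe_config(85, 180, 16), n_views = 16,
                          n_time = 64, dt_us = 2, c0_mps = 1509.15,
                          scan_type = "full")
  list(
    scan = scan, geom = build_aperture(scan),
    fullscan = fullscan, fgeom = build_aperture(fullscan),
    grid = centered_grid(32, 32, 16, voxel_mm = 3),
    phantom = phantom_spec(seed = seed + 99L, support_radius_mm = 42,
                           depth_decay_mm = 60),
    net_config = filter_net_config(n_levels = 3, base_channels = 4),
    train = train_config(learning_rate = 1e-3, epochs = 25L,
                         slab_fraction = 0.25, seed = seed + 1L,
                         n_train = 12L, n_val = 3L),
    n_train = 12L, n_val = 3L, n_test = 4L
  )
}

#' Run the desk-scale learned half-scan FBP study
#'
#' End-to-end scaled-down replication of the virtual imaging study:
#' generates the phantom ensemble, simulates noiseless half-scan training
#' pairs, initializes and gain-calibrates the linear filter, trains it with
#' the random-slab loss, and evaluates learned FBP against standard FBP on
#' half-scan and full-scan data for the held-out test phantoms.
#'
#' @param seed Integer seed for the whole study.
#' @param conditions Optionally a pre-built [desk_study_conditions()] list.
#' @param epochs Override for the training epochs (default from the
#'   conditions).
#' @return A list with the trained network (`net`), training `history`,
#'   the held-out `report` (a [compare_methods()] result), and the
#'   conditions used.
#' @export
run_desk_study <- function(seed = 1L, conditions = NULL, epochs = NULL) {
  cond <- if (is.null(conditions)) desk_study_conditions(seed) else conditions
  if (!is.null(epochs)) cond$train$epochs <- as.integer(epochs)
  n_total <- cond$n_train + cond$n_val + cond$n_test
  phs <- generate_ensemble(n_total, cond$phantom, cond$grid)
  idx_train <- seq_len(cond$n_train)
  idx_val <- cond$n_train + seq_len(cond$n_val)
  idx_test <- cond$n_train + cond$n_val + seq_len(cond$n_test)
  pairs <- lapply(phs[idx_train], make_training_pair,
                  geom = cond$geom, scan = cond$scan)
  vpairs <- lapply(phs[idx_val], make_training_pair,
                   geom = cond$geom, scan = cond$scan)
  tpairs <- lapply(phs[idx_test], make_training_pair,
                   geom = cond$geom, scan = cond$scan)
  net <- init_network(cond$net_config,
                      c(cond$scan$n_time, cond$scan$n_views,
                        cond$scan$probe$n_ring), seed = seed + 10L)
  net <- calibrate_filter_gain(net, pairs[1:2], cond$geom, cond$scan,
                               cond$grid)
  res <- train_filter(pairs, net, cond$train, cond$geom, cond$scan,
                      cond$grid, val_pairs = vpairs)
  truth <- lapply(tpairs, function(pr) pr$f)
  recs <- list(
    learned = lapply(tpairs, function(pr) {
      learned_fbp_reconstruct(res$net, pr$p, cond$geom, cond$scan, cond$grid)
    }),
    standard_half = lapply(tpairs, function(pr) {
      reconstruct_standard_fbp(pr$p, cond$geom, cond$scan, cond$grid)
    }),
    standard_full = lapply(tpairs, function(pr) {
      pf <- apply_forward(pr$f, cond$fgeom, cond$fullscan)
      reconstruct_standard_fbp(pf, cond$fgeom, cond$fullscan, cond$grid)
    }))
  list(net = res$net, history = res$history,
       report = compare_methods(truth, recs), conditions = cond)
}
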