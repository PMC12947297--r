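#' Training configuration for the learned half-scan filter
#'
#' @param learning_rate Adam step size (reference: 1e-4; small desk-scale
#'   studies may use a larger value, see the package vignette).
#' @param batch_size Samples per optimization step (reference: 1; only 1 is
#'   supported).
#' @param epochs Number of passes over the training pairs.
#' @param slab_fraction Fraction of the y extent used by the random-slab
#'   loss (reference: 85/340 = 1/4); 1 recovers the full-volume loss.
#' @param seed Integer seed controlling slab draws and any other
#'   stochasticity; training is deterministic given it.
#' @param optimizer Only `"adam"` (adaptive moments) is provided.
#' @param n_train,n_val Informational sample counts recorded with the run.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 1L,
                         epochs = 20L, slab_fraction = 0.25, seed = 1L,
                         optimizer = "adam", n_train = NA_integer_,
                         n_val = NA_integer_) {
  stopifnot(learning_rate > 0, slab_fraction > 0, slab_fraction <= 1,
            batch_size == 1L, optimizer == "adam")
  structure(
    list(learning_rate = learning_rate, batch_size = 1L,
         epochs = as.integer(epochs), slab_fraction = slab_fraction,
         seed = as.integer(seed), optimizer = "adam",
         n_train = n_train, n_val = n_val),
    class = "train_config"
  )
}

#' Generate a supervised (object, half-scan data) pair
#'
#' @param phantom An [object_volume()] inside the aperture's convex hull.
#' @param geom An [aperture_geometry][build_aperture].
#' @param scan A [scan_config()].
#' @param noise Optional [noise_spec()]; the reference training protocol is
#'   noiseless (`NULL`).
#' @return `list(f = phantom, p = apply_forward(phantom))`.
#' @export
make_training_pair <- function(phantom, geom, scan, noise = NULL) {
  p <- apply_forward(phantom, geom, scan)
  if (!is.null(noise)) p <- add_gaussian_noise(p, noise)
  list(f = phantom, p = p)
}

#' Mean squared error over a y slab
#'
#' The training loss: MSE between a reconstruction and the truth,
#' restricted to a contiguous range of y indices (the randomly drawn
#' partial volume that makes each backprojection cheap).  With the slab
#' covering all of y this is the ordinary full-volume MSE.
#'
#' @param f_hat_slab An [object_volume()] whose values on `slab` hold the
#'   reconstruction (entries outside the slab are ignored).
#' @param f The true [object_volume()].
#' @param slab Integer y-index range (1-based, contiguous).
#' @return Scalar mean squared error over the slab voxels.
#' @export
slab_loss <- function(f_hat_slab, f, slab) {
  stopifnot(inherits(f_hat_slab, "object_volume"), inherits(f, "object_volume"))
  slab <- as.integer(slab)
  if (min(slab) < 1L || max(slab) > f$grid$ny) stop("slab out of range")
  a <- f_hat_slab$values[, slab, , drop = FALSE]
  b <- f$values[, slab, , drop = FALSE]
  mean((a - b)^2)
}

# loss + full parameter gradient for one (f, p) pair on one slab.
# The composite is  L = MSE_slab(f, Hdagger F_theta p):  the gradient of the
# adjoint-backprojection w.r.t. its data input is the forward operator H
# applied to the (slab-supported) volume gradient.
.step_loss_grad <- function(net, pair, geom, scan, grid, slab) {
  x <- array(pair$p$values, c(dim(pair$p$values), 1L))
  fw <- filter_forward(net, x, keep_cache = TRUE)
  pf <- pressure_data(scan, array(fw$y, dim(pair$p$values)))
  fhat <- apply_adjoint(pf, geom, scan, grid, voxel_subset = slab)
  res <- fhat$values[, slab, , drop = FALSE] -
    pair$f$values[, slab, , drop = FALSE]
  nslab <- length(res)
  loss <- mean(res^2)
  gvol <- array(0, dim(fhat$values))
  gvol[, slab, ] <- 2 * res / nslab
  # dL/d(filtered data) = H applied to the upstream volume gradient
  gdata <- .cpp_forward(as.numeric(gvol),
                        c(grid$nx, grid$ny, grid$nz), grid$origin_mm,
                        grid$voxel_mm, geom$positions_mm,
                        scan$n_time, scan$n_views, scan$probe$n_ring,
                        scan$dt_us, c0_mm_per_us(scan))
  gy <- array(gdata, c(dim(pair$p$values), 1L))
  bw <- filter_backward(net, fw$cache, gy)
  list(loss = loss, grads = bw$grads)
}

#' Calibrate the output gain of a freshly initialized filter
#'
#' The matched adjoint is deliberately not normalized, so the composite
#' `Hdagger F_theta p` of a freshly initialized network is off from the
#' object scale by a large constant factor that gradient descent would
#' spend many steps recovering.  This initialization step computes the
#' least-squares scalar gain `alpha = <Hdagger F p, f> / |Hdagger F p|^2`
#' over the supplied pairs and folds it into the final projection weights
#' (the network being linear, this rescales its output exactly).
#' Deterministic; changes only the overall scale, not the filter shape.
#'
#' @param net A freshly initialized [filter_network][init_network].
#' @param pairs One or more training pairs from [make_training_pair()].
#' @param geom,scan,grid Acquisition geometry and grid.
#' @return The rescaled network.
#' @export
calibrate_filter_gain <- function(net, pairs, geom, scan, grid) {
  stopifnot(inherits(net, "filter_network"), length(pairs) >= 1)
  num <- 0; den <- 0
  for (pr in pairs) {
    fh <- learned_fbp_reconstruct(net, pr$p, geom, scan, grid)
    num <- num + sum(fh$values * pr$f$values)
    den <- den + sum(fh$values^2)
  }
  if (den == 0) stop("degenerate network output: zero energy")
  net$params$head$w <- net$params$head$w * (num / den)
  net
}

#' Train the data-filtering network
#'
#' Approximately solves the supervised objective
#' `argmin_theta mean_k MSE(f_k, Hdagger F_theta p_k)` with Adam,
#' single-sample steps, and a uniformly random contiguous y slab drawn per
#' step.  The wave operators are fixed linear maps; only the filter
#' parameters are updated.  Deterministic given `cfg$seed`.
#'
#' @param pairs List of pairs from [make_training_pair()], all sharing one
#'   scan and grid.
#' @param net A freshly initialized (or partially trained)
#'   [filter_network][init_network].
#' @param cfg A [train_config()].
#' @param geom,scan,grid The shared acquisition geometry and target grid.
#' @param val_pairs Optional held-out pairs; full-volume validation MSE is
#'   recorded each epoch and the best-epoch parameters are retained.
#' @return `list(net, history)` where `history` is a data frame with one
#'   row per epoch (`epoch`, `train_loss`, `val_loss`).
#' @export
train_filter <- function(pairs, net, cfg, geom, scan, grid,
                         val_pairs = NULL) {
  stopifnot(inherits(net, "filter_network"), inherits(cfg, "train_config"),
            length(pairs) >= 1)
  theta <- flatten_params(net$params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  it <- 0L
  slab_len <- max(1L, round(cfg$slab_fraction * grid$ny))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(val = Inf, theta = theta)
  with_local_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(pairs))
      ep_loss <- 0
      for (k in ord) {
        start <- sample.int(grid$ny - slab_len + 1L, 1L)
        slab <- start:(start + slab_len - 1L)
        sg <- .step_loss_grad(net, pairs[[k]], geom, scan, grid, slab)
        if (!is.finite(sg$loss)) {
          stop(sprintf("non-finite training loss at epoch %d (step %d)", ep, it))
        }
        ep_loss <- ep_loss + sg$loss
        g <- flatten_params(sg$grads)
        it <- it + 1L
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mhat <- m / (1 - beta1^it)
        vhat <- v / (1 - beta2^it)
        theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        net$params <- unflatten_params(net$params, theta)
      }
      val <- NA_real_
      if (!is.null(val_pairs)) {
        val <- mean(vapply(val_pairs, function(pr) {
          fh <- learned_fbp_reconstruct(net, pr$p, geom, scan, grid)
          mean((fh$values - pr$f$values)^2)
        }, numeric(1)))
        if (val < best$val) {
          best$val <- val; best$theta <- theta
        }
      }
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / length(pairs), val_loss = val))
    }
  })
  if (!is.null(val_pairs) && is.finite(best$val)) {
    net$params <- unflatten_params(net$params, best$theta)
  }
  list(net = net, history = history)
}

#' Learned half-scan FBP reconstruction
#'
#' The full learned pipeline: filter the half-scan data with the trained
#' network, then backproject with the matched adjoint,
#' `f_hat = Hdagger F_theta p`.  For noisy measurements the caller should
#' apodize first with [gaussian_lowpass()].
#'
#' @param net A trained [filter_network][init_network].
#' @param p A [pressure_data()].
#' @param geom,scan,grid Acquisition geometry and reconstruction grid.
#' @return An [object_volume()].
#' @export
learned_fbp_reconstruct <- function(net, p, geom, scan, grid) {
  apply_adjoint(apply_filter(net, p), geom, scan, grid)
}

#' Write a training history as CSV
#' @param history Data frame from [train_filter()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_training_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
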