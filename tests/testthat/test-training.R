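test_that("training pairs are deterministic and carry signal energy", {
  cond <- desk_study_conditions(seed = 3)
  grid <- cond$grid
  zero <- object_volume(grid, array(0, c(grid$nx, grid$ny, grid$nz)))
  zp <- make_training_pair(zero, cond$geom, cond$scan)
  expect_true(all(zp$p$values == 0))
  ph <- generate_phantom(cond$phantom, grid)
  p1 <- make_training_pair(ph, cond$geom, cond$scan)
  p2 <- make_training_pair(generate_phantom(cond$phantom, grid),
                           cond$geom, cond$scan)
  expect_identical(p1$p$values, p2$p$values)
  expect_gt(sum(p1$p$values^2), 0)
})

test_that("slab loss restricts the MSE to the requested y range", {
  grid <- centered_grid(8, 8, 4, voxel_mm = 6)
  f <- random_volume(grid, 2)
  # perfect reconstruction on the slab: zero loss
  expect_equal(slab_loss(f, f, 3:4), 0)
  # constant offset c: loss c^2
  off <- object_volume(grid, f$values + 0.7)
  expect_equal(slab_loss(off, f, 3:4), 0.49, tolerance = 1e-12)
  # slab covering everything equals the full-volume MSE
  g <- random_volume(grid, 3)
  expect_equal(slab_loss(g, f, 1:8), mean((g$values - f$values)^2))
  expect_error(slab_loss(f, f, 7:9), "out of range")
})

test_that("loss gradients match finite differences through H-dagger", {
  scan <- tiny_scan(n_ring = 4, n_views = 4, n_time = 16, dt_us = 10)
  geom <- build_aperture(scan)
  grid <- centered_grid(8, 8, 4, voxel_mm = 6)
  net <- init_network(filter_net_config(n_levels = 2, base_channels = 2),
                      c(16, 4, 4), seed = 3)
  set.seed(5)
  f <- random_volume(grid, 15, sd = 0.5)
  pair <- list(f = f, p = random_pressure(scan, 16))
  slab <- 3:4
  sg <- pactfbp:::.step_loss_grad(net, pair, geom, scan, grid, slab)
  g <- flatten_params(sg$grads)
  theta0 <- flatten_params(net$params)
  lossfn <- function(th) {
    net2 <- net
    net2$params <- unflatten_params(net$params, th)
    fh <- apply_adjoint(apply_filter(net2, pair$p), geom, scan, grid,
                        voxel_subset = slab)
    mean((fh$values[, slab, ] - f$values[, slab, ])^2)
  }
  expect_equal(sg$loss, lossfn(theta0), tolerance = 1e-12)
  set.seed(9)
  idx <- sample(length(theta0), 20)
  eps <- 1e-5
  for (i in idx) {
    tp <- theta0; tp[i] <- tp[i] + eps
    tm <- theta0; tm[i] <- tm[i] - eps
    fd <- (lossfn(tp) - lossfn(tm)) / (2 * eps)
    if (abs(fd) < 1e-12 && abs(g[i]) < 1e-12) next
    expect_lt(abs(fd - g[i]) / max(abs(fd), abs(g[i])), 1e-4)
  }
})

test_that("gain calibration minimizes the single-scalar fit", {
  cond <- desk_study_conditions(seed = 5)
  ph <- generate_phantom(cond$phantom, cond$grid)
  pair <- make_training_pair(ph, cond$geom, cond$scan)
  net <- init_network(cond$net_config, c(64, 16, 8), seed = 4)
  cal <- calibrate_filter_gain(net, list(pair), cond$geom, cond$scan,
                               cond$grid)
  fh <- learned_fbp_reconstruct(cal, pair$p, cond$geom, cond$scan, cond$grid)
  # at the least-squares gain, d/dalpha ||alpha fh - f||^2 = 0
  expect_lt(abs(sum(fh$values * (fh$values - ph$values))) /
            sum(fh$values^2), 1e-8)
})

test_that("training reduces the loss and zero learning rate freezes it", {
  scan <- tiny_scan(n_ring = 4, n_views = 4, n_time = 16, dt_us = 10)
  geom <- build_aperture(scan)
  grid <- centered_grid(8, 8, 4, voxel_mm = 6)
  spec <- phantom_spec(seed = 40, support_radius_mm = 20,
                       n_blobs = c(1, 2), n_vessels = c(0, 0))
  ph <- generate_phantom(spec, grid)
  pair <- make_training_pair(ph, geom, scan)
  net0 <- init_network(filter_net_config(n_levels = 2, base_channels = 2),
                       c(16, 4, 4), seed = 6)
  net0 <- calibrate_filter_gain(net0, list(pair), geom, scan, grid)
  # frozen parameters under lr -> 0
  tc0 <- train_config(learning_rate = 1e-30, epochs = 2, seed = 8)
  frozen <- train_filter(list(pair), net0, tc0, geom, scan, grid)
  expect_equal(flatten_params(frozen$net$params),
               flatten_params(net0$params), tolerance = 1e-12)
  # a single-pair run cuts the training loss by at least half
  tc <- train_config(learning_rate = 2e-3, epochs = 40, seed = 8)
  res <- train_filter(list(pair), net0, tc, geom, scan, grid)
  expect_lt(min(res$history$train_loss),
            0.5 * res$history$train_loss[1])
  # deterministic given the seed
  res2 <- train_filter(list(pair), net0, tc, geom, scan, grid)
  expect_identical(res$history$train_loss, res2$history$train_loss)
})

test_that("learned pipeline is linear and zero maps to zero", {
  cond <- desk_study_conditions(seed = 2)
  net <- init_network(cond$net_config, c(64, 16, 8), seed = 1)
  z <- pressure_data(cond$scan, array(0, c(64, 16, 8)))
  expect_true(all(learned_fbp_reconstruct(net, z, cond$geom, cond$scan,
                                          cond$grid)$values == 0))
  p <- random_pressure(cond$scan, 33)
  r1 <- learned_fbp_reconstruct(net, p, cond$geom, cond$scan, cond$grid)
  r2 <- learned_fbp_reconstruct(net, pressure_data(cond$scan, 2 * p$values),
                                cond$geom, cond$scan, cond$grid)
  expect_equal(r2$values, 2 * r1$values, tolerance = 1e-10)
})
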