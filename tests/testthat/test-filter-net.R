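test_that("configuration invariants and channel schedule hold", {
  cfg <- filter_net_config(n_levels = 7, base_channels = 8)
  expect_equal(channel_schedule(cfg), c(8, 16, 32, 64, 128, 256, 512))
  cfg4 <- filter_net_config(n_levels = 4, base_channels = 8)
  expect_equal(channel_schedule(cfg4), c(8, 16, 32, 64))
  expect_error(filter_net_config(n_levels = 1), "n_levels")
  expect_error(filter_net_config(strictly_linear = FALSE))
  # time/view extents must survive the stride-2 tower
  expect_error(init_network(filter_net_config(n_levels = 3), c(62, 16, 8)),
               "incompatible input dims")
})

test_that("network parameter count is fixed by the schedule", {
  net <- init_network(filter_net_config(n_levels = 3, base_channels = 4),
                      c(64, 16, 8), seed = 1)
  # enc convs: 125*(1*4 + 4*8 + 8*16), downs: 27*(16+64), ups: 8*(8*4+16*8),
  # decs: 125*(8*4 + 16*8), head: 4, ring pads: 2 sides x (9 taps x edge x
  # pad 2) per block, edge clamped to the ring extent 8/4/2 per level
  expect_equal(n_parameters(net),
               125 * (4 + 32 + 128) + 27 * (16 + 64) + 8 * (32 + 128) +
               125 * (32 + 128) + 4 + 2 * 9 * 2 * (5 + 4 + 2 + 5 + 4))
  # deterministic initialization
  net2 <- init_network(filter_net_config(n_levels = 3, base_channels = 4),
                       c(64, 16, 8), seed = 1)
  expect_identical(flatten_params(net$params), flatten_params(net2$params))
})

test_that("padding is cyclic in views, zero in time, learned on the ring", {
  set.seed(4)
  x <- array(rnorm(8 * 6 * 7 * 2), c(8, 6, 7, 2))
  out <- pad_block_input(x, pad_w = 2, ring_pad = NULL)
  expect_equal(dim(out), c(12, 10, 11, 2))
  # time: appended slices are exactly zero
  expect_true(all(out[c(1, 2, 11, 12), , , ] == 0))
  # view: first wrap slice equals the last interior view slice
  expect_equal(out[3:10, 1, 3:9, ], x[, 5, , ])
  expect_equal(out[3:10, 2, 3:9, ], x[, 6, , ])
  expect_equal(out[3:10, 9, 3:9, ], x[, 1, , ])
  # ring zeros without learned padding
  expect_true(all(out[3:10, , c(1, 2, 10, 11), ] == 0))
  # learned padding with zero weights reduces to zero padding
  zw <- list(left = array(0, c(9, 5, 2)), right = array(0, c(9, 5, 2)))
  outz <- pad_block_input(x, 2, zw)
  expect_equal(outz, out)
  # learned padding is a linear map of the edge slices
  set.seed(5)
  w <- list(left = array(rnorm(9 * 5 * 2), c(9, 5, 2)),
            right = array(rnorm(9 * 5 * 2), c(9, 5, 2)))
  o1 <- pad_block_input(x, 2, w)
  o2 <- pad_block_input(2 * x, 2, w)
  expect_equal(o2, 2 * o1, tolerance = 1e-13)
})

test_that("the filter network is strictly linear", {
  scan <- tiny_scan(n_ring = 8, n_views = 16, n_time = 64)
  net <- init_network(filter_net_config(n_levels = 3, base_channels = 4),
                      c(64, 16, 8), seed = 7)
  z <- pressure_data(scan, array(0, c(64, 16, 8)))
  expect_true(all(apply_filter(net, z)$values == 0))
  p1 <- random_pressure(scan, 1)
  p2 <- random_pressure(scan, 2)
  f1 <- apply_filter(net, p1)
  f2 <- apply_filter(net, p2)
  f3 <- apply_filter(net, pressure_data(scan, 3 * p1$values))
  expect_lt(max(abs(f3$values - 3 * f1$values)) / max(abs(f3$values)), 1e-4)
  fs <- apply_filter(net, pressure_data(scan, p1$values + p2$values))
  expect_lt(max(abs(fs$values - f1$values - f2$values)) /
            max(abs(fs$values)), 1e-4)
  expect_error(apply_filter(net, random_pressure(tiny_scan(4, 8, 32), 1)),
               "shape mismatch")
})

test_that("the filter commutes with view shifts by the downsampling factor", {
  scan <- tiny_scan(n_ring = 8, n_views = 16, n_time = 64)
  net <- init_network(filter_net_config(n_levels = 3, base_channels = 4),
                      c(64, 16, 8), seed = 7)
  p <- random_pressure(scan, 3)
  k <- 4L  # 2^(n_levels - 1)
  sh <- function(x) x[, c((k + 1):16, 1:k), , drop = FALSE]
  f <- apply_filter(net, p)
  fsh <- apply_filter(net, pressure_data(scan, sh(p$values)))
  expect_lt(max(abs(fsh$values - sh(f$values))) / max(abs(f$values)), 1e-4)
})

test_that("odd ring extents are handled by learned entry padding", {
  scan <- tiny_scan(n_ring = 5, n_views = 8, n_time = 32)
  net <- init_network(filter_net_config(n_levels = 3, base_channels = 2),
                      c(32, 8, 5), seed = 2)
  expect_equal(net$ring_pad_entry, 3L)
  p <- random_pressure(scan, 4)
  out <- apply_filter(net, p)
  expect_equal(dim(out$values), c(32, 8, 5))
  out3 <- apply_filter(net, pressure_data(scan, 3 * p$values))
  expect_lt(max(abs(out3$values - 3 * out$values)) /
            max(abs(out3$values)), 1e-4)
})

test_that("checkpoints round-trip with config and weights embedded", {
  net <- init_network(filter_net_config(n_levels = 2, base_channels = 2),
                      c(16, 4, 4), seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_filter_network(net, path)
  back <- load_filter_network(path)
  expect_equal(back, net)
  scan <- tiny_scan(n_ring = 4, n_views = 4, n_time = 16, dt_us = 10)
  p <- random_pressure(scan, 5)
  expect_identical(apply_filter(back, p)$values, apply_filter(net, p)$values)
})
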