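test_that("forward operator is linear and vanishes on the zero object", {
  scan <- tiny_scan()
  geom <- build_aperture(scan)
  grid <- centered_grid(16, 16, 8, voxel_mm = 5)
  zero <- object_volume(grid, array(0, c(16, 16, 8)))
  expect_true(all(apply_forward(zero, geom, scan)$values == 0))
  f <- random_volume(grid, seed = 3)
  p1 <- apply_forward(f, geom, scan)
  f2 <- object_volume(grid, 2 * f$values)
  p2 <- apply_forward(f2, geom, scan)
  expect_equal(p2$values, 2 * p1$values, tolerance = 1e-14)
})

test_that("adjoint identity holds to double precision on random instances", {
  scan <- tiny_scan(n_ring = 4, n_views = 8, n_time = 64)
  geom <- build_aperture(scan)
  grid <- centered_grid(16, 16, 8, voxel_mm = 5)
  for (seed in 1:5) {
    f <- random_volume(grid, seed)
    p <- random_pressure(scan, seed + 100)
    Hf <- apply_forward(f, geom, scan)
    Htp <- apply_adjoint(p, geom, scan, grid)
    lhs <- sum(Hf$values * p$values)
    rhs <- sum(f$values * Htp$values)
    denom <- sqrt(sum(Hf$values^2)) * sqrt(sum(p$values^2))
    expect_lt(abs(lhs - rhs) / denom, 1e-10)
  }
})

test_that("slab-restricted adjoint equals the full adjoint bit-exactly", {
  scan <- tiny_scan()
  geom <- build_aperture(scan)
  grid <- centered_grid(16, 16, 8, voxel_mm = 5)
  p <- random_pressure(scan, 7)
  full <- apply_adjoint(p, geom, scan, grid)
  slab <- apply_adjoint(p, geom, scan, grid, voxel_subset = 9:16)
  expect_identical(slab$values[, 9:16, ], full$values[, 9:16, ])
  expect_true(all(slab$values[, 1:8, ] == 0))
  expect_error(apply_adjoint(p, geom, scan, grid, voxel_subset = c(1, 3)),
               "contiguous")
})

test_that("closed-form N-wave has the documented shape", {
  scan <- tiny_scan(n_time = 512, dt_us = 0.1)
  center <- c(0, 0, -30); a <- 6; A <- 2
  c0 <- 1.50915
  # place the transducer so the shell-center arrival d/c0 = 30 us falls on
  # a sample: the sampled wave is then exactly odd about that sample
  d <- c0 * 30
  rq <- c(0, 0, -30 - d)
  sig <- analytic_sphere_signal(center, a, A, rq, scan)
  expect_equal(sig[301], 0)
  expect_equal(sig[301 + 1:100], -sig[301 - 1:100], tolerance = 1e-14)
  expect_lt(abs(sum(sig)), 1e-12)
  # leading-edge peak A*a/(2d), sampled within one dt of the edge
  expect_equal(max(sig), A * a / (2 * d), tolerance = c0 * 0.1 / a)
  expect_error(analytic_sphere_signal(center, a, A, c(0, 0, -29), scan),
               "inside the sphere")
})

test_that("simulated sphere signal approaches the closed form and converges", {
  # agreement is assessed both raw and within the band the voxel grid can
  # represent (both signals apodized at HWHM = voxel transit time h/c0);
  # the raw error against the unbounded-bandwidth N-wave is dominated by
  # its two edge discontinuities (see the vignette)
  errs <- sapply(c(2, 1, 0.5), function(h) {
    n <- round(18 / h); if (n %% 2 == 1) n <- n + 1
    scan <- scan_config(probe_config(85, 90, 1), n_views = 1, n_time = 1024,
                        dt_us = 0.1, c0_mps = 1509.15)
    geom <- build_aperture(scan)
    grid <- volume_grid(n, n, n, h,
                        origin_mm = c(-(n - 1) / 2 * h, -(n - 1) / 2 * h,
                                      -30 - (n - 1) / 2 * h))
    ph <- sphere_phantom(grid, c(0, 0, -30), 6, 1)
    sim <- apply_forward(ph, geom, scan)
    ora <- oracle_sphere_data(scan, geom, c(0, 0, -30), 6, 1)
    hwhm <- h / 1.50915
    raw <- rel_l2(sim$values, ora$values)
    band <- rel_l2(gaussian_lowpass(sim, hwhm)$values,
                   gaussian_lowpass(ora, hwhm)$values)
    c(raw = raw, band = band)
  })
  # error decreases monotonically as the voxel size halves
  expect_true(all(diff(errs["raw", ]) < 0))
  expect_true(all(diff(errs["band", ]) < 0))
  # within the grid's representable band, agreement is a few percent
  expect_lt(errs["band", 3], 0.05)
  expect_lt(errs["raw", 3], 0.25)
})

test_that("forward model is covariant under z-rotations by a view step", {
  scan <- tiny_scan(n_ring = 3, n_views = 4, n_time = 96)
  geom <- build_aperture(scan)
  grid <- centered_grid(12, 12, 6, voxel_mm = 6)
  set.seed(21)
  vals <- array(rnorm(12 * 12 * 6), c(12, 12, 6))
  f <- object_volume(grid, vals)
  # rotate the volume by 90 degrees about z: (x, y) -> (-y, x) maps the
  # centered grid onto itself exactly
  rot_vals <- aperm(vals, c(2, 1, 3))[12:1, , , drop = FALSE]
  dim(rot_vals) <- c(12, 12, 6)
  f_rot <- object_volume(grid, rot_vals)
  p <- apply_forward(f, geom, scan)
  p_rot <- apply_forward(f_rot, geom, scan)
  shifted <- p$values[, c(4, 1, 2, 3), , drop = FALSE]
  expect_lt(rel_l2(p_rot$values, shifted), 1e-6)
})

test_that("volumes and pressure tensors round-trip through raw float32", {
  grid <- centered_grid(6, 5, 4, voxel_mm = 4)
  f <- random_volume(grid, 12)
  path <- withr::local_tempfile(fileext = ".f32")
  write_raw_f32(f, path)
  back <- read_raw_f32(path)
  expect_equal(back$grid, grid)
  expect_equal(back$values, f$values, tolerance = 1e-6)  # float32 rounding
  scan <- tiny_scan(n_ring = 3, n_views = 4, n_time = 16)
  p <- random_pressure(scan, 13)
  path2 <- withr::local_tempfile(fileext = ".f32")
  write_raw_f32(p, path2)
  back2 <- read_raw_f32(path2)
  expect_equal(back2$scan, scan)
  expect_equal(back2$values, p$values, tolerance = 1e-6)
})

test_that("measurement vector flattening follows the q*Nt + w ordering", {
  scan <- tiny_scan(n_ring = 3, n_views = 2, n_time = 4)
  d <- c(4, 2, 3)
  vals <- array(seq_len(prod(d)), d)
  p <- pressure_data(scan, vals)
  flat <- as_measurement_vector(p)
  # sample (w, v, j): position q*Nt + w + 1 with q = v*Nr + j
  for (w in 0:3) for (v in 0:1) for (j in 0:2) {
    q <- v * 3 + j
    expect_identical(flat[q * 4 + w + 1], vals[w + 1, v + 1, j + 1])
  }
})
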