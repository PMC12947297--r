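# Shared fixtures: every input is generated in code at test time.

# small half-scan acquisition used by most operator tests
tiny_scan <- function(n_ring = 4L, n_views = 8L, n_time = 64L, dt_us = 2,
                      angle = 90, scan_type = "half") {
  scan_config(probe_config(85, angle, n_ring), n_views = n_views,
              n_time = n_time, dt_us = dt_us, c0_mps = 1509.15,
              scan_type = scan_type)
}

# pressure tensor filled with seeded Gaussian noise
random_pressure <- function(scan, seed) {
  d <- c(scan$n_time, scan$n_views, scan$probe$n_ring)
  set.seed(seed)
  pressure_data(scan, array(rnorm(prod(d)), d))
}

random_volume <- function(grid, seed, sd = 1) {
  set.seed(seed)
  object_volume(grid, array(rnorm(grid$nx * grid$ny * grid$nz, sd = sd),
                            c(grid$nx, grid$ny, grid$nz)))
}

# closed-form uniform-sphere signals sampled at every transducer
oracle_sphere_data <- function(scan, geom, center, a, A = 1) {
  arr <- array(0, c(scan$n_time, scan$n_views, scan$probe$n_ring))
  Nr <- scan$probe$n_ring
  for (q in seq_len(nrow(geom$positions_mm))) {
    v <- (q - 1) %/% Nr
    j <- (q - 1) %% Nr
    arr[, v + 1, j + 1] <-
      analytic_sphere_signal(center, a, A, geom$positions_mm[q, ], scan)
  }
  pressure_data(scan, arr)
}

rel_l2 <- function(x, y) sqrt(sum((x - y)^2) / sum(y^2))
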