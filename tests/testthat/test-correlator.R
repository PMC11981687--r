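# Sensor timing arithmetic and the multi-pixel correlator.

test_that("sensor timing reproduces the published exposure settings", {
  expect_equal(exposure_time(250, 1), 10e-6)
  expect_equal(exposure_time(64, 2), 2.56e-6)
  expect_equal(exposure_time(1, 1), 40e-9)
  expect_error(exposure_time(300, 1), "1..250")
  expect_equal(frame_rate(3e-6), 333333)
  expect_equal(frame_rate(1), 1)
  # the tabulated 92,200 fps at 10.81 us is overhead-dependent; the
  # reciprocal lands within a percent of it
  expect_lt(abs(frame_rate(10.81e-6) - 92200) / 92200, 0.01)
})

test_that("delay grids cover both tau_max conventions", {
  g <- delay_grid(3e-6, 168, include_zero = FALSE)
  expect_equal(g$tau_max, 504e-6)
  g16 <- delay_grid(3.37e-6, 16)
  expect_equal(g16$delays[1], 0)
  expect_equal(g16$tau_max, 15 * 3.37e-6)
  expect_equal(g16$delays[13], 40.44e-6)  # 12th nonzero delay, ~40.4 us
})

test_that("curves per averaging window match the published table", {
  expect_equal(curves_per_window(0.125, 56, 3e-6), 744L)
  expect_equal(curves_per_window(0.1, 168, 3e-6), 198L)
  expect_equal(curves_per_window(0.1, 46, 10.81e-6), 201L)
  expect_equal(curves_per_window(1, 10, 0.1), 1L)
  expect_warning(n <- curves_per_window(1e-6, 56, 3e-6), "shorter")
  expect_equal(n, 0L)
})

make_stream <- function(counts_matrix, dt = 1e-6) {
  structure(list(counts = counts_matrix, frame_period_s = dt,
                 exposure_s = dt, n_frames = nrow(counts_matrix),
                 n_pixels = ncol(counts_matrix)),
            class = "frame_stream")
}

test_that("single-pixel g2 matches hand-derivable cases", {
  grid <- delay_grid(1e-6, 3)
  st_const <- make_stream(matrix(1L, 12, 1))
  expect_equal(compute_g2_pixel(st_const, 1, grid), rep(1, 3))
  st_alt <- make_stream(matrix(rep(c(1L, 0L), 5), ncol = 1))
  g2 <- compute_g2_pixel(st_alt, 1, grid)
  expect_equal(g2[2], 0)
  expect_equal(g2[3], 2)
  # zero-intensity window flagged invalid, not NaN-propagated
  st0 <- make_stream(matrix(0L, 10, 1))
  expect_true(all(is.na(compute_g2_pixel(st0, 1, grid))))
})

test_that("vectorized correlator equals the brute-force pair enumeration", {
  set.seed(31)
  for (L in c(50, 333, 1000)) {
    x <- as.integer(runif(L) < 0.2)
    st <- make_stream(matrix(x, ncol = 1))
    k <- 12L
    expect_equal(compute_g2_pixel(st, 1, delay_grid(1e-6, k)),
                 oracle_g2_bruteforce(x, k), tolerance = 1e-12)
  }
  # and on an actual simulated speckle stream
  det <- detector_sim_params(n_pixels = 2, n_frames = 800,
                             mean_rate = 0.1, seed = 9)
  st <- simulate_speckle_photons(default_props(), shallow_geom(), 1e-8, det)
  expect_equal(compute_g2_pixel(st, 2, delay_grid(st$frame_period_s, 16)),
               oracle_g2_bruteforce(as.numeric(st$counts[, 2]), 16),
               tolerance = 1e-12)
})

test_that("g2 estimator is invariant under time reversal", {
  set.seed(8)
  x <- as.integer(runif(400) < 0.3)
  st <- make_stream(matrix(x, ncol = 1))
  st_rev <- make_stream(matrix(rev(x), ncol = 1))
  grid <- delay_grid(1e-6, 10)
  expect_equal(compute_g2_pixel(st, 1, grid),
               compute_g2_pixel(st_rev, 1, grid), tolerance = 1e-12)
})

test_that("pixel_window_g2 agrees with per-pixel per-window calls", {
  set.seed(12)
  counts <- matrix(as.integer(runif(600) < 0.25), 200, 3)
  st <- make_stream(counts)
  a <- pixel_window_g2(st, 8, 50)
  grid <- delay_grid(1e-6, 8)
  for (px in 1:3) for (w in 1:4) {
    expect_equal(a[, w, px],
                 compute_g2_pixel(st, px, grid,
                                  window = c((w - 1) * 50e-6, 50e-6)),
                 tolerance = 1e-12)
  }
})

test_that("average_g2 is the unweighted mean with provenance", {
  grid <- delay_grid(1e-6, 2)
  rec <- average_g2(cbind(c(1.2, 1.0), c(1.0, 1.0)), grid)
  expect_equal(rec$g2, c(1.1, 1.0))
  expect_equal(rec$n_curves_averaged, 2L)
  # idempotent on identical curves
  rec2 <- average_g2(cbind(c(1.3, 1.1), c(1.3, 1.1), c(1.3, 1.1)), grid)
  expect_equal(rec2$g2, c(1.3, 1.1))
  # invalid (NA) curves are dropped and not counted
  rec3 <- average_g2(cbind(c(1.2, 1.0), c(NA, NA)), grid)
  expect_equal(rec3$g2, c(1.2, 1.0))
  expect_equal(rec3$n_curves_averaged, 1L)
  expect_error(average_g2(matrix(NA_real_, 2, 1), grid), "no valid")
})

test_that("averaged-g2 noise scales as the inverse square root of M", {
  det <- detector_sim_params(n_pixels = 1024, n_frames = 6000,
                             coherent_fraction = 0.5, mean_rate = 0.1,
                             seed = 21)
  st <- simulate_speckle_photons(default_props(), shallow_geom(), 1e-8, det)
  g2a <- pixel_window_g2(st, 8, 200)                    # 30 windows
  ms <- c(1, 16, 256, 1024)
  sds <- sapply(ms, function(m) {
    avg <- apply(g2a[, , seq_len(m), drop = FALSE], c(1, 2), mean)
    mean(apply(avg[-1, , drop = FALSE], 1, sd))
  })
  slope <- unname(coef(lm(log(sds) ~ log(ms)))[2])
  expect_lt(abs(slope + 0.5), 0.05)
})

test_that("on-board 16-delay mode is the per-span restriction identity", {
  det <- detector_sim_params(n_pixels = 4, n_frames = 640,
                             mean_rate = 0.3, seed = 17)
  st <- simulate_speckle_photons(default_props(), shallow_geom(), 1e-8, det)
  # constant stream: all 16 values are 1
  st_const <- make_stream(matrix(1L, 320, 2), dt = st$frame_period_s)
  rec_c <- onboard16_g2(st_const, 16 * st$frame_period_s)[[1]]
  expect_equal(rec_c$g2, rep(1, 16))
  # one window = one span per pixel: equals compute_g2_pixel on that span
  recs <- onboard16_g2(st, 16 * st$frame_period_s)
  grid <- delay_grid(st$frame_period_s, 16)
  manual <- sapply(1:4, function(px)
    compute_g2_pixel(st, px, grid, window = c(0, 16 * st$frame_period_s)))
  valid <- !apply(is.na(manual), 2, any)
  expect_equal(recs[[1]]$g2, rowMeans(manual[, valid, drop = FALSE]),
               tolerance = 1e-12)
  # multi-span windows carry the Table-2 curve count arithmetic
  recs2 <- correlate_frame_stream(st, window_length = 64 * st$frame_period_s,
                                  n_delays = 16L)
  cur <- pixel_window_g2(st, 16, 16)[, 1:4, , drop = FALSE]
  n_valid <- sum(apply(cur, c(2, 3), function(v) !any(is.na(v))))
  expect_equal(recs2[[1]]$n_curves_averaged, n_valid)
})
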