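# Speckle-matching optics, the semi-infinite g1 model, the Siegert relation,
# the pulsatile waveform generator and the photon-stream simulator.

test_that("speckle-matched fiber-sensor distances reproduce the two setups", {
  expect_equal(speckle_spot_distance(785, 200, 6.9), 1.758, tolerance = 1e-3)
  expect_equal(speckle_spot_distance(785, 1500, 6), 11.465, tolerance = 1e-3)
  # linearity in the target speckle diameter
  expect_equal(speckle_spot_distance(785, 200, 2 * 6.9),
               2 * speckle_spot_distance(785, 200, 6.9))
  expect_error(speckle_spot_distance(-785, 200, 6.9), "positive")
})

test_that("g1 matches an independent transcription of the closed form", {
  props <- default_props()
  for (rho in c(1.5, 4)) {
    geom <- probe_geometry(sds = rho)
    for (tau in c(1e-6, 1e-5, 1e-4)) {
      expect_equal(
        g1_semi_infinite(props, geom, 1e-8, tau),
        oracle_g1_semi_infinite(0.17, 8, 1.4, 1.0, 785, rho, 1e-8, tau),
        tolerance = 1e-10)
    }
  }
})

test_that("g1 normalization, limits and monotonicity", {
  props <- default_props(); geom <- shallow_geom()
  taus <- c(0, 1e-6, 1e-5, 1e-4, 1e-3)
  expect_equal(g1_semi_infinite(props, geom, 1e-8, 0), 1.0)
  expect_equal(g1_semi_infinite(props, geom, 0, taus), rep(1, 5))
  g <- g1_semi_infinite(props, geom, 1e-8, taus)
  expect_true(all(diff(g) < 0))
  expect_lt(g1_semi_infinite(props, geom, 1e-8, 1e-2), 1e-6)
  # faster flow and larger separation both decay g1 faster at every tau > 0
  g_fast <- g1_semi_infinite(props, geom, 5e-8, taus[-1])
  expect_true(all(g_fast < g[-1]))
  g_deep <- g1_semi_infinite(props, deep_geom(), 1e-8, taus[-1])
  expect_true(all(g_deep < g[-1]))
  expect_error(g1_semi_infinite(props, geom, -1, taus), "non-negative")
})

test_that("Siegert relation maps g1 to g2", {
  expect_equal(g2_from_g1(1, 0.3), 1.3)
  expect_equal(g2_from_g1(0, 0.5), 1.0)
  expect_equal(g2_from_g1(0.5, 0.2), 1.05)
  expect_error(g2_from_g1(0.5, 1.2), "beta")
})

test_that("irradiance of the study's illumination spot is below the MPE", {
  expect_lt(beam_irradiance(100, 4), 300)
  expect_true(mpe_compliant(100, 4))
  expect_false(mpe_compliant(1000, 4))
})

test_that("pulsatile waveform generator produces the expected cycles", {
  p <- pulse_waveform_params(pulse_rate = 1.2, jitter_sd = 0.01)
  tr <- make_pulsatile_bfi(p, duration = 15, sample_rate = 10, seed = 3)
  mk <- attr(tr, "markers")
  n_sp <- sum(mk$kind == "SP")
  expect_true(abs(n_sp - 18) <= 1)  # rate x duration, +/- jitter/boundary
  expect_true(all(tr$bfi >= p$bfi_baseline * (1 - 1e-12)))
  # flat waveform when the systolic amplitude is zero
  p0 <- pulse_waveform_params(pulse_rate = 1.2, systolic_amplitude = 0)
  tr0 <- make_pulsatile_bfi(p0, 10, 10, seed = 1)
  expect_equal(tr0$bfi, rep(p0$bfi_baseline, nrow(tr0)))
  # ground-truth markers are extrema of the generated samples
  for (i in which(mk$kind == "SP")) {
    j <- mk$index[i]
    expect_true(tr$bfi[j] >= tr$bfi[j - 1] && tr$bfi[j] >= tr$bfi[j + 1])
  }
  for (i in which(mk$kind == "DN")) {
    j <- mk$index[i]
    expect_true(tr$bfi[j] < tr$bfi[j - 1] && tr$bfi[j] < tr$bfi[j + 1])
  }
  expect_warning(pulse_waveform_params(pulse_rate = 3.5), "band")
})

test_that("photon streams are seed-deterministic and rate-calibrated", {
  det <- detector_sim_params(n_pixels = 64, n_frames = 3000,
                             coherent_fraction = 0.5, mean_rate = 0.05,
                             dark_rate = 1e-3, seed = 42)
  st1 <- simulate_speckle_photons(default_props(), shallow_geom(), 1e-8, det)
  st2 <- simulate_speckle_photons(default_props(), shallow_geom(), 1e-8, det)
  expect_identical(st1$counts, st2$counts)
  # mean event rate within 3 binomial standard errors of the target
  p_tot <- 0.05 + 1e-3
  se <- sqrt(p_tot * (1 - p_tot) / length(st1$counts))
  expect_lt(abs(mean(st1$counts) - p_tot), 3 * se)
  # memory budget refusal
  det_big <- detector_sim_params(n_pixels = 1024, n_frames = 1e6,
                                 max_elements = 1e6)
  expect_error(simulate_speckle_photons(default_props(), shallow_geom(),
                                        1e-8, det_big), "chunk")
})

test_that("zero coherent fraction gives i.i.d. events with flat g2", {
  det <- detector_sim_params(n_pixels = 128, n_frames = 4000,
                             coherent_fraction = 0, mean_rate = 0.08,
                             dark_rate = 0.001, seed = 5)
  st <- simulate_speckle_photons(default_props(), shallow_geom(), 1e-8, det)
  g2a <- pixel_window_g2(st, 8, 4000)
  avg <- rowMeans(g2a[, 1, ])
  se <- apply(g2a[, 1, ], 1, sd) / sqrt(128)
  expect_true(all(abs(avg[-1] - 1) < 3 * se[-1]))
})

test_that("pixel-averaged measured g2 matches the Siegert closed form", {
  props <- default_props(); geom <- shallow_geom()
  det <- detector_sim_params(n_pixels = 1024, exposure = 3.37e-6,
                             n_frames = 3000, coherent_fraction = 0.5,
                             mean_rate = 0.05, dark_rate = 1e-4, seed = 7)
  st <- simulate_speckle_photons(props, geom, 1e-8, det)
  g2a <- pixel_window_g2(st, 16, 3000)
  avg <- rowMeans(g2a[, 1, ])
  se <- apply(g2a[, 1, ], 1, sd) / sqrt(det$n_pixels)
  grid <- onboard_grid()
  expected <- model_g2(props, geom, 1e-8, det$coherent_fraction^2,
                       grid$delays)
  # tau = 0 is shot-noise dominated for binary counts; compare nonzero delays
  expect_true(all(abs(avg[-1] - expected[-1]) < 3 * se[-1]))
})

test_that("frame streams round-trip through the plain-text container", {
  det <- detector_sim_params(n_pixels = 8, n_frames = 200, seed = 2)
  st <- simulate_speckle_photons(default_props(), shallow_geom(), 1e-8, det)
  dir <- withr::local_tempdir()
  write_frame_stream(st, dir)
  st2 <- read_frame_stream(dir)
  expect_identical(st$counts, st2$counts)
  expect_equal(st$exposure_s, st2$exposure_s)
  expect_equal(st$bfi_trace$bfi, st2$bfi_trace$bfi)
})
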