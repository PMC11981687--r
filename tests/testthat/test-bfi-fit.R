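# Model fitting: offset correction, bounded least squares, exclusion rule,
# and the early-slope metric.

test_that("model_g2 composes g1 and the Siegert relation", {
  props <- default_props(); geom <- shallow_geom()
  grid <- onboard_grid()
  expect_equal(model_g2(props, geom, 0, 0.3, grid$delays),
               rep(1.3, 16))
  expect_equal(model_g2(props, geom, 1e-8, 0, grid$delays), rep(1, 16))
  expect_equal(model_g2(props, geom, 1e-8, 0.25, grid$delays),
               g2_from_g1(g1_semi_infinite(props, geom, 1e-8, grid$delays),
                          0.25),
               tolerance = 1e-12)
})

test_that("tail-anchored offset correction recovers constructed offsets", {
  props <- default_props(); geom <- deep_geom()
  grid <- delay_grid(1e-5, 16)   # tail fully decorrelated at this flow
  clean <- make_model_record(props, geom, 1e-8, 0.25, grid)
  corr <- correct_g2_offset(clean)
  expect_lt(abs(corr$offset_applied), 2e-3)  # tail already decorrelated
  biased <- clean; biased$g2 <- biased$g2 + 0.02
  corr2 <- correct_g2_offset(biased)
  expect_equal(corr2$offset_applied, -0.02, tolerance = 5e-3)
  # undecayed curve: correction skipped with a warning
  flat <- make_model_record(props, shallow_geom(), 1e-10, 0.25, grid)
  expect_warning(out <- correct_g2_offset(flat), "skipped")
  expect_equal(out$g2, flat$g2)
})

test_that("noiseless fits recover bfi and beta to high precision", {
  props <- default_props()
  for (geom in list(shallow_geom(), deep_geom())) {
    grid <- onboard_grid()
    for (truth in list(c(1e-8, 0.25), c(6.3e-8, 0.12), c(3e-9, 0.55))) {
      rec <- make_model_record(props, geom, truth[1], truth[2], grid)
      fit <- fit_bfi(rec, props, geom,
                     fit_options(offset_correction = FALSE))
      expect_lt(abs(fit$bfi - truth[1]) / truth[1], 1e-6)
      expect_lt(abs(fit$beta - truth[2]), 1e-6)
      expect_true(fit$valid)
    }
  }
})

test_that("noisy fits recover the median bfi within 5 percent", {
  props <- default_props(); geom <- deep_geom()
  grid <- onboard_grid()
  set.seed(404)
  bfis <- replicate(100, {
    rec <- make_model_record(props, geom, 1e-8, 0.25, grid, noise_sd = 0.005)
    fit_bfi(rec, props, geom, fit_options(offset_correction = FALSE))$bfi
  })
  expect_lt(abs(median(bfis) - 1e-8) / 1e-8, 0.05)
})

test_that("a flat g2 curve drives beta to its bound and is flagged", {
  props <- default_props(); geom <- shallow_geom()
  grid <- onboard_grid()
  rec <- correlation_record(0, 0.125, rep(1, 16), grid)
  fit <- fit_bfi(rec, props, geom, fit_options(offset_correction = FALSE))
  expect_lt(fit$beta, 1e-4)
  expect_false(fit$valid)
})

test_that("fitted bfi increases strictly with the true bfi", {
  props <- default_props(); geom <- deep_geom()
  grid <- onboard_grid()
  truths <- 10^seq(-8.5, -7.5, length.out = 10)
  fitted <- vapply(truths, function(b) {
    rec <- make_model_record(props, geom, b, 0.25, grid)
    fit_bfi(rec, props, geom, fit_options(offset_correction = FALSE))$bfi
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("g2 decays faster at 4 cm than at 1.5 cm separation", {
  props <- default_props()
  tau <- seq(0, 5e-4, by = 1e-6)
  half_decay <- function(geom) {
    g2 <- model_g2(props, geom, 1e-8, 0.25, tau)
    tau[which(g2 - 1 <= 0.125)[1]]
  }
  expect_lt(half_decay(deep_geom()), half_decay(shallow_geom()))
})

test_that("traces assemble from uniformly spaced records", {
  props <- default_props(); geom <- deep_geom()
  grid <- onboard_grid()
  recs <- lapply(0:74, function(w)
    make_model_record(props, geom, 1e-8, 0.25, grid,
                      window_start = w * 0.1, window_length = 0.1))
  tr <- trace_from_records(recs, props, geom,
                           fit_options(offset_correction = FALSE))
  expect_equal(nrow(tr), 75)
  expect_equal(attr(tr, "sample_rate"), 10)
  expect_equal(max(tr$time) + 0.1, 7.5)
  recs8 <- lapply(0:119, function(w)
    make_model_record(props, geom, 1e-8, 0.25, grid,
                      window_start = w * 0.125, window_length = 0.125))
  tr8 <- trace_from_records(recs8, props, geom,
                            fit_options(offset_correction = FALSE))
  expect_equal(attr(tr8, "sample_rate"), 8)
  expect_equal(max(tr8$time) + 0.125, 15)
  expect_error(trace_from_records(list(), props, geom), "empty")
  expect_error(trace_from_records(recs[c(1:5, 7:10)], props, geom,
                                  fit_options(offset_correction = FALSE)),
               "gaps")
})

test_that("trial exclusion uses a strict median-residual threshold", {
  mk_trace <- function(res) {
    tr <- data.frame(time = seq_along(res), bfi = 1e-8, residual = res,
                     valid = TRUE)
    class(tr) <- c("bfi_trace", "data.frame"); tr
  }
  trials <- list(
    good = mk_trace(rep(0.01, 10)),
    boundary = mk_trace(rep(c(0.01, 0.05), 5)),  # median exactly 0.03
    bad = mk_trace(rep(0.05, 10)))
  out <- exclude_trials(trials)
  expect_setequal(out$kept, c("good", "boundary"))
  expect_equal(out$excluded, "bad")
})

test_that("early g2 slope is the OLS slope over initial delays", {
  grid <- delay_grid(1e-6, 8)
  g2_lin <- 1.3 - 1000 * grid$delays
  rec <- correlation_record(0, 0.1, g2_lin, grid)
  expect_equal(early_slope_metric(rec, 5), -1000, tolerance = 1e-9)
  rec_const <- correlation_record(0, 0.1, rep(1.2, 8), grid)
  expect_equal(early_slope_metric(rec_const, 5), 0)
  expect_error(early_slope_metric(rec, 1), "at least 2")
  # |slope| grows monotonically with the simulated bfi
  props <- default_props(); geom <- deep_geom()
  og <- onboard_grid()
  slopes <- vapply(10^seq(-9, -8, length.out = 8), function(b) {
    early_slope_metric(make_model_record(props, geom, b, 0.25, og), 5)
  }, numeric(1))
  expect_true(all(slopes < 0))
  expect_true(all(diff(abs(slopes)) > 0))
})
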