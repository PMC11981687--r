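# Independent oracles used across the suite. These are deliberately written
# as literal, slow transcriptions, independent of the package's vectorized
# implementations.

# Brute-force normalized intensity autocorrelation: explicit double loop over
# all frame pairs fully inside the window, normalized by the squared window
# mean.
oracle_g2_bruteforce <- function(x, n_delays) {
  L <- length(x)
  mu <- sum(x) / L
  out <- numeric(n_delays)
  for (k in 0:(n_delays - 1)) {
    acc <- 0
    npair <- 0
    for (t in 1:(L - k)) {
      acc <- acc + x[t] * x[t + k]
      npair <- npair + 1
    }
    out[k + 1] <- (acc / npair) / mu^2
  }
  out
}

# Second, literal transcription of the extrapolated-zero-boundary
# semi-infinite Green's-function field autocorrelation (scalar tau).
oracle_g1_semi_infinite <- function(mu_a, mu_sp, n_in, n_out, lambda_nm,
                                    rho, bfi, tau) {
  lambda_cm <- lambda_nm * 1e-7
  k0 <- 2 * pi * n_in / lambda_cm
  n_rel <- n_in / n_out
  reff <- -1.440 * n_rel^-2 + 0.710 * n_rel^-1 + 0.668 + 0.0636 * n_rel
  z0 <- 1 / mu_sp
  zb <- (2 / 3) * (1 + reff) / ((1 - reff) * mu_sp)
  r1 <- sqrt(rho * rho + z0 * z0)
  rb <- sqrt(rho * rho + (z0 + 2 * zb) * (z0 + 2 * zb))
  green <- function(tau_s) {
    kd <- sqrt(3 * mu_a * mu_sp + mu_sp^2 * 6 * k0^2 * bfi * tau_s)
    exp(-kd * r1) / r1 - exp(-kd * rb) / rb
  }
  green(tau) / green(0)
}

# Analytic correlation record on a given grid (optionally with additive
# noise), for fit tests that do not need photon-level simulation.
make_model_record <- function(props, geom, bfi, beta, grid,
                              noise_sd = 0, window_start = 0,
                              window_length = 0.125) {
  g2 <- model_g2(props, geom, bfi, beta, grid$delays)
  if (noise_sd > 0) g2 <- g2 + stats::rnorm(length(g2), 0, noise_sd)
  correlation_record(window_start, window_length, g2, grid,
                     n_pixels_averaged = 1024L, n_curves_averaged = 1L)
}

default_props <- function() optical_properties()
shallow_geom <- function() probe_geometry(sds = 1.5)
deep_geom <- function() probe_geometry(sds = 4, fiber_diameter = 1500,
                                       pixel_active_diameter = 6)
onboard_grid <- function(dt = 3.37e-6) delay_grid(dt, 16)
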