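#' Parameters of the synthetic pulsatile BFI waveform
#'
#' Describes one cardiac-cycle template: a rapid systolic upstroke to the
#' systolic peak (SP), a fall to the dicrotic notch (DN), a partial rebound to
#' the diastolic peak (DP) and a decay to the diastolic end (DE) at the cycle
#' boundary. Cycle periods jitter independently around `1/pulse_rate`.
#'
#' @param pulse_rate Fundamental pulse frequency (Hz). Values outside the
#'   physiological detection band 0.33-2.65 Hz trigger a warning (downstream
#'   marker analysis will reject such traces).
#' @param bfi_baseline Diastolic-end BFI level (cm^2/s).
#' @param systolic_amplitude SP minus DE excursion (cm^2/s).
#' @param notch_depth Fractional dip of the dicrotic notch below the systolic
#'   peak, in (0, 1).
#' @param notch_delay Time from SP to DN (s); must be < 0.4 s so the notch
#'   detector window applies. At fast rates the effective delay is clamped to
#'   35% of the cycle period to keep the template coherent.
#' @param diastolic_peak_height Fractional rebound after the notch, in (0, 1).
#' @param jitter_sd Cycle-to-cycle period jitter standard deviation (s).
#' @param systolic_fraction Fraction of the cycle taken by the upstroke.
#' @return An object of class `pulse_waveform_params`.
#' @export
pulse_waveform_params <- function(pulse_rate = 1.07, bfi_baseline = 1e-8,
                                  systolic_amplitude = 6e-9,
                                  notch_depth = 0.35, notch_delay = 0.3,
                                  diastolic_peak_height = 0.3,
                                  jitter_sd = 0.02,
                                  systolic_fraction = 0.18) {
  if (pulse_rate <= 0 || bfi_baseline < 0 || systolic_amplitude < 0 ||
      jitter_sd < 0)
    stop("rates and amplitudes must be non-negative, pulse_rate positive")
  if (notch_depth <= 0 || notch_depth >= 1 ||
      diastolic_peak_height <= 0 || diastolic_peak_height >= 1)
    stop("notch_depth and diastolic_peak_height must lie in (0, 1)")
  if (notch_delay >= 0.4)
    stop("notch_delay must be < 0.4 s (dicrotic-notch detector window)")
  if (pulse_rate < 0.33 || pulse_rate > 2.65)
    warning("pulse_rate outside the 0.33-2.65 Hz physiological band")
  structure(list(pulse_rate = pulse_rate, bfi_baseline = bfi_baseline,
                 systolic_amplitude = systolic_amplitude,
                 notch_depth = notch_depth, notch_delay = notch_delay,
                 diastolic_peak_height = diastolic_peak_height,
                 jitter_sd = jitter_sd,
                 systolic_fraction = systolic_fraction),
            class = "pulse_waveform_params")
}

# Evaluate the normalized single-cycle template (0 at DE, 1 at SP) at times
# `tt` inside a cycle starting at `t0` with period `p`. Returns the anchor
# times as an attribute.
.cycle_values <- function(tt, t0, p, params) {
  t_sp <- t0 + params$systolic_fraction * p
  # keep the notch in mid-cycle at fast rates so the template stays coherent
  t_dn <- t_sp + min(params$notch_delay, 0.35 * p)
  t_dp <- t_dn + 0.4 * (t0 + p - t_dn)
  dn_h <- 1 - params$notch_depth
  dp_h <- dn_h + params$diastolic_peak_height * (1 - dn_h)
  y <- numeric(length(tt))
  seg <- findInterval(tt, c(t0, t_sp, t_dn, t_dp, t0 + p),
                      rightmost.closed = TRUE)
  s1 <- seg == 1
  if (any(s1)) {
    u <- (tt[s1] - t0) / (t_sp - t0)
    y[s1] <- 0.5 * (1 - cos(pi * u))
  }
  s2 <- seg == 2
  if (any(s2)) {
    u <- (tt[s2] - t_sp) / (t_dn - t_sp)
    y[s2] <- dn_h + (1 - dn_h) * 0.5 * (1 + cos(pi * u))
  }
  s3 <- seg == 3
  if (any(s3)) {
    u <- (tt[s3] - t_dn) / (t_dp - t_dn)
    y[s3] <- dn_h + (dp_h - dn_h) * 0.5 * (1 - cos(pi * u))
  }
  s4 <- seg >= 4
  if (any(s4)) {
    u <- (tt[s4] - t_dp) / (t0 + p - t_dp)
    y[s4] <- dp_h * (1 - pmin(u, 1))
  }
  attr(y, "anchors") <- c(sp = t_sp, dn = t_dn, dp = t_dp, de = t0 + p)
  y
}

#' Generate a ground-truth pulsatile BFI trace
#'
#' Builds a sampled BFI time series from the cycle template in
#' [pulse_waveform_params()], with seeded cycle-period jitter, and records the
#' ground-truth marker locations (both the continuous-time anchor and the
#' sample-level extremum of the generated samples) for closed-loop testing of
#' the marker detector.
#'
#' @param params [pulse_waveform_params()].
#' @param duration Trace duration (s); must cover at least two pulse periods.
#' @param sample_rate Sampling rate of the BFI trace (Hz), e.g. 8 or 10.
#' @param seed Integer seed for the period jitter.
#' @return A `bfi_trace`: data.frame with columns `time`, `bfi`, `valid`, and
#'   attributes `sample_rate`, `markers` (ground truth) and `segment_label`.
#' @export
#' @examples
#' tr <- make_pulsatile_bfi(pulse_waveform_params(), duration = 15,
#'                          sample_rate = 10, seed = 1)
#' head(tr)
make_pulsatile_bfi <- function(params, duration, sample_rate, seed = 1L) {
  stopifnot(inherits(params, "pulse_waveform_params"))
  if (duration * sample_rate < 2 * sample_rate / params$pulse_rate)
    stop("duration must cover at least two pulse periods")
  n <- floor(duration * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  y <- numeric(n)
  truth <- list()
  with_seed(seed, {
    t0 <- 0
    while (t0 < duration) {
      p <- 1 / params$pulse_rate
      if (params$jitter_sd > 0)
        p <- max(0.5 / params$pulse_rate, p + stats::rnorm(1, 0, params$jitter_sd))
      idx <- which(tt >= t0 & tt < t0 + p)
      if (length(idx)) {
        yv <- .cycle_values(tt[idx], t0, p, params)
        y[idx] <- yv
        truth[[length(truth) + 1L]] <-
          list(start = t0, period = p, idx = idx,
               anchors = attr(yv, "anchors"))
      }
      t0 <- t0 + p
    }
  })
  bfi <- params$bfi_baseline + params$systolic_amplitude * y
  trace <- data.frame(time = tt, bfi = bfi, valid = TRUE)
  attr(trace, "sample_rate") <- sample_rate
  attr(trace, "markers") <- .truth_markers(truth, tt, bfi, duration, params)
  attr(trace, "params") <- params
  class(trace) <- c("bfi_trace", "data.frame")
  trace
}

# Sample-level ground-truth markers: per fully contained cycle, the extrema of
# the generated samples (SP = argmax over the cycle, DN = argmin between SP
# and DP anchor, DP = argmax between DN and the late-cycle decay, DE = argmin
# between consecutive sample-level SPs). DN/DP are reported only when they are
# distinct strict extrema of the sampled series.
.truth_markers <- function(truth, tt, bfi, duration, params) {
  rows <- list()
  if (params$systolic_amplitude == 0 || !length(truth))
    return(data.frame(kind = character(), time = numeric(),
                      index = integer(), bfi = numeric()))
  full <- Filter(function(cy) cy$start + cy$period <= duration &&
                   length(cy$idx) >= 3, truth)
  sp_idx <- integer()
  for (cy in full) {
    i <- cy$idx[which.max(bfi[cy$idx])]
    sp_idx <- c(sp_idx, i)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "SP", time = tt[i], index = i, bfi = bfi[i],
      anchor = unname(cy$anchors["sp"]))
    seg <- cy$idx[tt[cy$idx] > cy$anchors["sp"] & tt[cy$idx] <= cy$anchors["dp"]]
    if (length(seg) >= 1) {
      dn <- seg[which.min(bfi[seg])]
      seg2 <- cy$idx[tt[cy$idx] >= tt[dn] & tt[cy$idx] <= cy$anchors["de"]]
      dp <- seg2[which.max(bfi[seg2])]
      strict_min <- dn > 1 && dn < length(bfi) &&
        bfi[dn] < bfi[dn - 1] && bfi[dn] < bfi[dn + 1]
      strict_max <- dp > 1 && dp < length(bfi) &&
        bfi[dp] > bfi[dp - 1] && bfi[dp] > bfi[dp + 1]
      if (dn != dp && strict_min && strict_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "DN", time = tt[dn], index = dn, bfi = bfi[dn],
          anchor = unname(cy$anchors["dn"]))
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "DP", time = tt[dp], index = dp, bfi = bfi[dp],
          anchor = unname(cy$anchors["dp"]))
      }
    }
  }
  # DE: sample-level minima between consecutive SPs
  sp_idx <- sort(sp_idx)
  if (length(sp_idx) >= 2) {
    for (j in seq_len(length(sp_idx) - 1)) {
      between <- (sp_idx[j] + 1):(sp_idx[j + 1] - 1)
      if (length(between)) {
        de <- between[which.min(bfi[between])]
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "DE", time = tt[de], index = de, bfi = bfi[de],
          anchor = NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$time), , drop = FALSE]
}

#' Construct a BFI trace from raw vectors
#'
#' @param time Sample times (s), uniformly spaced.
#' @param bfi BFI values (cm^2/s).
#' @param sample_rate Sampling rate (Hz); inferred from `time` if `NULL`.
#' @param valid Logical validity flags.
#' @param segment_label Optional label, e.g. "control_before".
#' @return A `bfi_trace` object.
#' @export
bfi_trace <- function(time, bfi, sample_rate = NULL, valid = TRUE,
                      segment_label = NA_character_) {
  stopifnot(length(time) == length(bfi))
  if (is.null(sample_rate)) {
    if (length(time) < 2) stop("need sample_rate or >= 2 samples")
    sample_rate <- 1 / stats::median(diff(time))
  }
  trace <- data.frame(time = time, bfi = bfi,
                      valid = rep_len(valid, length(time)))
  attr(trace, "sample_rate") <- sample_rate
  attr(trace, "segment_label") <- segment_label
  class(trace) <- c("bfi_trace", "data.frame")
  trace
}
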