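# Pulse-rate estimation and pulse-marker detection on BFI traces.

# Strict local extrema of a series (both neighbors strictly smaller/larger).
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] > x[i + 1]]
}

# Greedy minimum-separation peak selection (tallest first, ties to the
# earlier sample), mirroring the usual findpeaks MinPeakDistance behavior.
.select_peaks <- function(x, cand, min_sep_samples) {
  ord <- cand[order(-x[cand], cand)]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep_samples))
      kept <- c(kept, i)
  }
  sort(kept)
}

#' Pulse rate from the BFI spectrum
#'
#' Frequency of the largest non-DC peak of the 4x zero-padded magnitude
#' spectrum of the mean-subtracted trace. A pulse is reported only when that
#' peak lies inside the physiological band (default 0.33-2.65 Hz); otherwise
#' an explicit no-pulse result is returned. The native spectral resolution is
#' 1/duration.
#'
#' @param trace A `bfi_trace` (uniformly sampled; sample rate must exceed
#'   twice the upper band edge).
#' @param band Search band in Hz.
#' @return List with `detected` (logical), `rate_hz` (`NA` when not
#'   detected), `peak_hz` (argmax frequency regardless of band) and
#'   `resolution_hz`.
#' @export
estimate_pulse_rate <- function(trace, band = c(0.33, 2.65)) {
  sr <- attr(trace, "sample_rate")
  if (is.null(sr)) stop("trace needs a sample_rate attribute")
  if (sr <= 2 * band[2])
    stop("sample rate must exceed twice the upper band edge")
  x <- trace$bfi[trace$valid]
  n <- length(x)
  if (n < 8) stop("trace too short for spectral rate estimation")
  x <- x - mean(x)
  nfft <- 4L * n
  mag <- Mod(stats::fft(c(x, numeric(nfft - n))))
  half <- floor(nfft / 2)
  freq <- (1:(half - 1)) / (nfft / sr)
  mag <- mag[2:half]
  peak <- which.max(mag)
  peak_hz <- freq[peak]
  detected <- peak_hz >= band[1] && peak_hz <= band[2]
  list(detected = detected,
       rate_hz = if (detected) peak_hz else NA_real_,
       peak_hz = peak_hz,
       resolution_hz = sr / n)
}

#' Pulse rate from a beat count
#'
#' `n_pulses / duration`, reported to two decimals. Two rates whose counts
#' differ by one beat over the same segment differ by `1/duration`, the
#' quantization uncertainty of count-based rates.
#'
#' @param n_pulses Number of beats counted.
#' @param duration Segment duration (s).
#' @return Rate in Hz, rounded to 2 decimals.
#' @export
#' @examples
#' pulse_rate_from_counts(8, 7.5)  # 1.07 Hz
pulse_rate_from_counts <- function(n_pulses, duration) {
  if (duration <= 0) stop("duration must be positive")
  round(n_pulses / duration, 2)
}

#' Detect pulse markers in a BFI trace
#'
#' Systolic peaks (SP) are strict local maxima separated by at least
#' `0.6 / pulse_rate` seconds (the minimal-distance rule, read as a time);
#' diastolic ends (DE) are the minima between consecutive SPs; dicrotic
#' notches (DN) are the earliest strict local minimum within `(SP,
#' SP + dn_window]` that precedes the next DE; diastolic peaks (DP) are
#' strict local maxima strictly between DN and the next DE. Beats whose
#' DN and DP cannot be resolved as distinct strict extrema (too-coarse
#' sampling) are dropped and counted in `discarded_dn_dp`. Partial cycles at
#' the trace boundaries yield no markers.
#'
#' @param trace A `bfi_trace`.
#' @param pulse_rate Pulse rate (Hz), e.g. from [estimate_pulse_rate()].
#' @param dn_window Notch search window after each SP (s), default 0.4.
#' @return A `pulse_marker_set`: list of data.frames `sp`, `de`, `dn`, `dp`
#'   (columns `time`, `index`, `bfi`), `pulse_rate`, `discarded_dn_dp`.
#' @export
detect_markers <- function(trace, pulse_rate, dn_window = 0.4) {
  if (!is.finite(pulse_rate) || pulse_rate <= 0)
    stop("valid pulse_rate required")
  x <- trace$bfi
  tt <- trace$time
  sr <- attr(trace, "sample_rate")
  min_sep <- 0.6 / pulse_rate * sr
  cand <- .local_maxima(x)
  if (length(cand) < 2) stop("fewer than 2 systolic peak candidates")
  sp <- .select_peaks(x, cand, min_sep)
  if (length(sp) < 2) stop("fewer than 2 systolic peaks")
  de <- integer(); dn <- integer(); dp <- integer(); discarded <- 0L
  for (j in seq_len(length(sp) - 1)) {
    seg <- (sp[j] + 1L):(sp[j + 1L] - 1L)
    if (!length(seg)) next
    de_j <- seg[which.min(x[seg])]
    de <- c(de, de_j)
    win <- seg[tt[seg] > tt[sp[j]] & tt[seg] <= tt[sp[j]] + dn_window &
                 seg < de_j]
    strict_min <- win[x[win] < x[win - 1L] & x[win] < x[win + 1L]]
    if (length(strict_min)) {
      dn_j <- strict_min[1L]  # earliest strict local minimum
      between <- seg[seg > dn_j & seg < de_j]
      strict_max <- between[x[between] > x[between - 1L] &
                              x[between] > x[between + 1L]]
      if (length(strict_max)) {
        dp_j <- strict_max[which.max(x[strict_max])]
        dn <- c(dn, dn_j)
        dp <- c(dp, dp_j)
      } else {
        discarded <- discarded + 1L
      }
    } else {
      discarded <- discarded + 1L
    }
  }
  mk <- function(idx) data.frame(time = tt[idx], index = idx, bfi = x[idx])
  structure(list(sp = mk(sp), de = mk(de), dn = mk(dn), dp = mk(dp),
                 pulse_rate = pulse_rate, discarded_dn_dp = discarded),
            class = "pulse_marker_set")
}

#' @export
print.pulse_marker_set <- function(x, ...) {
  cat("pulse_marker_set:", nrow(x$sp), "SP,", nrow(x$de), "DE,",
      nrow(x$dn), "DN,", nrow(x$dp), "DP;",
      x$discarded_dn_dp, "unresolved DN/DP beats\n")
  invisible(x)
}

#' Pulsatility index and pulse-averaged BFI metrics
#'
#' `PI = (<BFI>_SP - <BFI>_DE) / <BFI>`, where `<BFI>` is the mean over all
#' valid samples of the trial and the marker averages run over all detected
#' systolic peaks and diastolic ends. PI is invariant to rescaling the trace.
#'
#' @param trace A `bfi_trace`.
#' @param markers A `pulse_marker_set` from [detect_markers()].
#' @return List with `pi`, `mean_bfi`, `mean_sp`, `mean_de`.
#' @export
pulsatility_index <- function(trace, markers) {
  if (!nrow(markers$sp) || !nrow(markers$de))
    stop("need at least one SP and one DE marker")
  mean_bfi <- mean(trace$bfi[trace$valid])
  mean_sp <- mean(markers$sp$bfi)
  mean_de <- mean(markers$de$bfi)
  list(pi = (mean_sp - mean_de) / mean_bfi,
       mean_bfi = mean_bfi, mean_sp = mean_sp, mean_de = mean_de)
}
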