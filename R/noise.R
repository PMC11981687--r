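# Marker-conditioned g2 noise and the multi-speckle sqrt(M) scaling law.

# Map marker times to the nearest record window start (ties to the earlier
# window); collisions keep both markers as separate draws, preserving n.
.marker_windows <- function(window_starts, marker_times) {
  vapply(marker_times, function(tm) {
    d <- abs(window_starts - tm)
    which(d == min(d))[1]
  }, integer(1))
}

#' Marker-conditioned g2 noise of one trial
#'
#' Treats all records at equivalent pulse phases (systolic peaks,
#' respectively diastolic ends) as repeated measurements under similar flow
#' conditions: the per-delay noise is the sample standard deviation (n-1
#' denominator) of g2(tau) across the marker-selected records, and the
#' average noise is its mean over delays.
#'
#' @param records List of [correlation_record()]s sharing one delay grid.
#' @param marker_times Times (s) of one marker family (>= 2 markers); each is
#'   mapped to the nearest record window.
#' @param delays `"nonzero"` (default) to average noise over all nonzero
#'   delays, `"all"` to include tau = 0, or an index vector into the grid.
#' @return List with `n_bar` (mean noise over delays), `per_delay_noise`,
#'   `tau`, `n_markers_used`.
#' @export
g2_noise_at_markers <- function(records, marker_times,
                                delays = c("nonzero", "all")) {
  if (length(marker_times) < 2)
    stop("need >= 2 markers for a defined standard deviation")
  grid <- records[[1]]$grid
  if (is.character(delays)) {
    delays <- match.arg(delays)
    idx <- if (delays == "nonzero") which(grid$delays > 0)
           else seq_along(grid$delays)
  } else idx <- delays
  starts <- vapply(records, `[[`, numeric(1), "window_start")
  sel <- .marker_windows(starts, marker_times)
  g2m <- vapply(records[sel], `[[`, numeric(grid$n_delays), "g2")
  per_delay <- apply(g2m[idx, , drop = FALSE], 1, stats::sd)
  list(n_bar = mean(per_delay), per_delay_noise = per_delay,
       tau = grid$delays[idx], n_markers_used = length(sel))
}

#' Noise summary for both marker families of one trial
#'
#' @param records List of [correlation_record()]s.
#' @param markers A `pulse_marker_set` from [detect_markers()].
#' @inheritParams g2_noise_at_markers
#' @return List with `n_bar_sp`, `n_bar_de` and the two full summaries.
#' @export
marker_noise_summary <- function(records, markers, delays = "nonzero") {
  sp <- g2_noise_at_markers(records, markers$sp$time, delays)
  de <- g2_noise_at_markers(records, markers$de$time, delays)
  list(n_bar_sp = sp$n_bar, n_bar_de = de$n_bar, sp = sp, de = de)
}

#' Noise versus number of averaged pixels
#'
#' For each pixel count M, a seeded random subset of M pixels (drawn without
#' replacement) is averaged per window, the per-delay standard deviation of
#' the averaged g2 is taken across repeated windows, and the mean over
#' nonzero delays gives the overall noise N(M). Independent pixels make the
#' noise scale as `M^(-1/2)`, the multi-speckle SNR parallelization law; the
#' fitted log-log slope is returned.
#'
#' @param stream A `frame_stream`, or a precomputed per-pixel/per-window g2
#'   array from [pixel_window_g2()].
#' @param pixel_counts Pixel counts M (each `<=` number of pixels).
#' @param n_delays,frames_per_window Correlator settings used when `stream`
#'   is a frame stream.
#' @param seed Seed for the subset draws.
#' @return List with `table` (data.frame `m`, `n_bar`) and `slope` of
#'   log(N) on log(M).
#' @export
noise_vs_pixels <- function(stream, pixel_counts, n_delays = 16L,
                            frames_per_window = 200L, seed = 1L) {
  g2a <- if (is.array(stream) && length(dim(stream)) == 3) stream
         else pixel_window_g2(stream, n_delays, frames_per_window)
  n_pix <- dim(g2a)[3]
  if (max(pixel_counts) > n_pix)
    stop("pixel count exceeds available pixels (", n_pix, ")")
  nz <- 2:dim(g2a)[1]  # drop the tau = 0 bin
  n_bar <- with_seed(seed, vapply(pixel_counts, function(m) {
    pick <- sample.int(n_pix, m)
    avg <- apply(g2a[, , pick, drop = FALSE], c(1, 2), mean)  # delays x windows
    mean(apply(avg[nz, , drop = FALSE], 1, stats::sd))
  }, numeric(1)))
  tab <- data.frame(m = pixel_counts, n_bar = n_bar)
  slope <- unname(stats::coef(stats::lm(log(n_bar) ~ log(m), data = tab))[2])
  list(table = tab, slope = slope)
}
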