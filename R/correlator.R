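#' Uniform delay grid of a software or on-board correlator
#'
#' @param dt Delay spacing (s), equal to the frame period.
#' @param n_delays Number of delays K.
#' @param include_zero If `TRUE` (default) the grid is `0, dt, ...,
#'   (K-1) dt` (the on-board convention, `tau_max = (K-1) dt`); if `FALSE` it
#'   is `dt, ..., K dt`, the convention in which a "delays per curve" count
#'   refers to nonzero delays only (`tau_max = K dt`).
#' @return An object of class `delay_grid` with fields `dt`, `n_delays`,
#'   `delays`, `tau_max`, `include_zero`.
#' @export
#' @examples
#' delay_grid(3e-6, 168, include_zero = FALSE)$tau_max  # 504 us
#' delay_grid(3.37e-6, 16)$delays[13]                   # 12th nonzero, ~40.4 us
delay_grid <- function(dt, n_delays, include_zero = TRUE) {
  if (dt <= 0 || n_delays < 1) stop("dt must be positive, n_delays >= 1")
  delays <- if (include_zero) (0:(n_delays - 1)) * dt else (1:n_delays) * dt
  structure(list(dt = dt, n_delays = as.integer(n_delays), delays = delays,
                 tau_max = max(delays), include_zero = include_zero),
            class = "delay_grid")
}

#' Sensor timing of a SPAD array
#'
#' The rolling-shutter array reads `n_rows` rows at 40 ns per row, so the
#' nominal exposure is `n_rows * 40 ns` per sensor half (both halves are read
#' concurrently; a second half doubles the pixel count, not the time). The
#' effective frame period may exceed the nominal exposure by an
#' overhead (wait states and clock cycles) that is sensor-dependent and left
#' as a free parameter.
#'
#' @param n_rows Rows read out (1..250).
#' @param n_halves Sensor halves active (1 or 2).
#' @param effective_frame_period Effective frame period (s); defaults to the
#'   nominal exposure (zero overhead).
#' @param mode `"raw_stream"` or `"onboard16"`.
#' @return An object of class `sensor_timing`.
#' @export
sensor_timing <- function(n_rows, n_halves = 1,
                          effective_frame_period = NULL,
                          mode = c("raw_stream", "onboard16")) {
  mode <- match.arg(mode)
  nominal <- exposure_time(n_rows, n_halves)
  if (is.null(effective_frame_period)) effective_frame_period <- nominal
  if (effective_frame_period < nominal)
    stop("effective_frame_period must be >= nominal exposure")
  structure(list(n_rows = as.integer(n_rows), n_halves = as.integer(n_halves),
                 row_time = 40e-9, nominal_exposure = nominal,
                 effective_frame_period = effective_frame_period,
                 mode = mode),
            class = "sensor_timing")
}

#' Nominal exposure time from the rows read out
#'
#' `t_exposure = n_rows * 40 ns` per sensor half.
#'
#' @param n_rows Rows read out, 1..250.
#' @param n_halves Sensor halves (1 or 2); read concurrently, so it does not
#'   multiply the time.
#' @return Exposure time in seconds.
#' @export
#' @examples
#' exposure_time(250, 1)  # 10 us
#' exposure_time(64, 2)   # 2.56 us
exposure_time <- function(n_rows, n_halves = 1) {
  if (n_rows < 1 || n_rows > 250) stop("n_rows must lie in 1..250")
  if (!n_halves %in% c(1, 2)) stop("n_halves must be 1 or 2")
  n_rows * 40e-9
}

#' Frame rate from the effective frame period
#'
#' @param effective_frame_period Frame period (s).
#' @return Frames per second, rounded to integer fps.
#' @export
#' @examples
#' frame_rate(3e-6)  # 333333 fps
frame_rate <- function(effective_frame_period) {
  if (effective_frame_period <= 0) stop("period must be positive")
  round(1 / effective_frame_period)
}

#' Autocorrelation curves per averaging window
#'
#' Number of non-overlapping sub-curves (spans of `n_delays` frames) that fit
#' in one temporal averaging window Delta-T:
#' `floor(window_length / (n_delays * effective_frame_period))`.
#'
#' @param window_length Averaging window Delta-T (s).
#' @param grid A [delay_grid()] or the number of delays per curve.
#' @param timing A [sensor_timing()] or the effective frame period (s).
#' @return Integer curve count (0 with a warning if the window is shorter
#'   than one curve span).
#' @export
#' @examples
#' curves_per_window(0.125, 56, 3e-6)  # 744
#' curves_per_window(0.1, 168, 3e-6)   # 198
curves_per_window <- function(window_length, grid, timing) {
  k <- if (inherits(grid, "delay_grid")) grid$n_delays else as.integer(grid)
  period <- if (inherits(timing, "sensor_timing"))
    timing$effective_frame_period else as.numeric(timing)
  n <- floor(window_length / (k * period))
  if (n < 1) {
    warning("window shorter than one curve span; 0 curves")
    return(0L)
  }
  as.integer(n)
}

# Lag-shrinking normalized intensity autocorrelation of one pixel stream `x`
# over delays 0..(k_max-1) frames: g2(k) = mean(x[t] x[t+k]) / mean(x)^2 with
# the numerator mean over all pairs fully inside the window. Returns NA curve
# (flagged invalid) when the window has zero mean intensity.
.g2_lagshrink <- function(x, n_delays) {
  L <- length(x)
  if (n_delays > L) stop("more delays than frames in window")
  mu <- mean(x)
  if (mu <= 0) return(rep(NA_real_, n_delays))
  vapply(0:(n_delays - 1L), function(k) {
    mean(x[seq_len(L - k)] * x[(1L + k):L]) / mu^2
  }, numeric(1))
}

#' Per-pixel g2 over one time window
#'
#' Normalized intensity autocorrelation `g2(tau_k) = <I(t) I(t+tau_k)> /
#' <I(t)>^2` of a single pixel, with time averages over all frame pairs that
#' fit entirely inside the window (lag-shrinking estimator).
#'
#' @param stream A `frame_stream`.
#' @param pixel Pixel index.
#' @param grid A [delay_grid()] with `include_zero = TRUE`.
#' @param window `c(start_s, length_s)` in stream time; default the full
#'   stream.
#' @return g2 values on the grid; all-`NA` (invalid) if the window has zero
#'   mean intensity.
#' @export
compute_g2_pixel <- function(stream, pixel, grid, window = NULL) {
  stopifnot(inherits(grid, "delay_grid"), grid$include_zero)
  dt <- stream$frame_period_s
  if (is.null(window)) window <- c(0, stream$n_frames * dt)
  i0 <- floor(window[1] / dt) + 1L
  i1 <- min(stream$n_frames, i0 + floor(window[2] / dt) - 1L)
  if (i0 < 1 || i1 > stream$n_frames || i1 < i0)
    stop("window outside stream")
  .g2_lagshrink(as.numeric(stream$counts[i0:i1, pixel]), grid$n_delays)
}

#' Per-pixel, per-window g2 array
#'
#' Vectorized lag-shrinking estimator over consecutive non-overlapping windows
#' of `frames_per_window` frames for every pixel at once.
#'
#' @param stream A `frame_stream` (or a frames x pixels numeric matrix).
#' @param n_delays Number of delays (including tau = 0).
#' @param frames_per_window Frames per window.
#' @return Array `[n_delays, n_windows, n_pixels]`; windows with zero mean
#'   intensity give `NA` curves.
#' @export
pixel_window_g2 <- function(stream, n_delays, frames_per_window) {
  counts <- if (inherits(stream, "frame_stream")) stream$counts else stream
  L <- as.integer(frames_per_window)
  if (n_delays > L) stop("more delays than frames per window")
  n_win <- nrow(counts) %/% L
  if (n_win < 1) stop("stream shorter than one window")
  m <- ncol(counts)
  a <- array(as.numeric(counts[seq_len(n_win * L), , drop = FALSE]),
             dim = c(L, n_win, m))
  mu <- colMeans(a, dims = 1)                      # n_win x m
  out <- array(NA_real_, dim = c(n_delays, n_win, m))
  for (k in 0:(n_delays - 1L)) {
    num <- colMeans(a[seq_len(L - k), , , drop = FALSE] *
                    a[(1L + k):L, , , drop = FALSE], dims = 1)
    out[k + 1L, , ] <- num / mu^2
  }
  bad <- mu <= 0
  if (any(bad)) {
    for (k in seq_len(n_delays)) out[k, , ][bad] <- NA_real_
  }
  out
}

#' A pixel- and window-averaged correlation record
#'
#' @param window_start Start time of the averaging window (s).
#' @param window_length Window length Delta-T (s).
#' @param g2 Averaged g2 values on `grid`.
#' @param grid A [delay_grid()].
#' @param n_pixels_averaged Pixels contributing.
#' @param n_curves_averaged Sub-curves per pixel contributing.
#' @param mean_rate Mean events/frame in the window.
#' @return An object of class `correlation_record`.
#' @export
correlation_record <- function(window_start, window_length, g2, grid,
                               n_pixels_averaged = 1L,
                               n_curves_averaged = 1L, mean_rate = NA_real_) {
  stopifnot(length(g2) == grid$n_delays)
  structure(list(window_start = window_start, window_length = window_length,
                 g2 = as.numeric(g2), grid = grid,
                 n_pixels_averaged = as.integer(n_pixels_averaged),
                 n_curves_averaged = as.integer(n_curves_averaged),
                 mean_rate = mean_rate),
            class = "correlation_record")
}

#' @export
print.correlation_record <- function(x, ...) {
  cat("correlation_record: window", format(x$window_start), "s +",
      format(x$window_length), "s;", x$grid$n_delays, "delays;",
      x$n_pixels_averaged, "pixels x", x$n_curves_averaged, "curves\n")
  invisible(x)
}

#' Unweighted mean of valid g2 curves
#'
#' Averages per-pixel / per-sub-window curves that share one delay grid;
#' invalid (all-`NA`) curves are dropped and counted in the provenance.
#'
#' @param curves A matrix (delays x curves) or list of g2 vectors.
#' @param grid The shared [delay_grid()].
#' @param window_start,window_length Provenance of the averaging window.
#' @param n_pixels Number of distinct pixels represented.
#' @param mean_rate Mean events/frame in the window.
#' @return A [correlation_record()].
#' @export
average_g2 <- function(curves, grid, window_start = 0,
                       window_length = NA_real_, n_pixels = NA_integer_,
                       mean_rate = NA_real_) {
  if (is.list(curves)) curves <- do.call(cbind, curves)
  if (is.null(dim(curves))) curves <- matrix(curves, ncol = 1)
  valid <- !apply(is.na(curves), 2, any)
  if (!any(valid)) stop("no valid curves to average")
  g2 <- rowMeans(curves[, valid, drop = FALSE])
  if (is.na(n_pixels)) n_pixels <- sum(valid)
  correlation_record(window_start, window_length, g2, grid,
                     n_pixels_averaged = n_pixels,
                     n_curves_averaged = sum(valid), mean_rate = mean_rate)
}

#' Full correlator pipeline: stream to averaged correlation records
#'
#' Emulates the study's averaging scheme: each averaging window Delta-T is
#' partitioned into consecutive non-overlapping spans of `n_delays` frames;
#' one lag-shrinking g2 curve is computed per span per pixel, and all valid
#' curves in the window are averaged into one [correlation_record()]
#' (matching the published curves-per-window arithmetic). With
#' `mode = "onboard16"` the grid is fixed at 16 delays (`tau_max` at 15 times
#' the frame period), emulating the on-board FPGA autocorrelator.
#'
#' @param stream A `frame_stream`.
#' @param window_length Averaging window Delta-T (s).
#' @param n_delays Delays per curve (including tau = 0); forced to 16 in
#'   on-board mode.
#' @param mode `"raw"` or `"onboard16"`.
#' @param pixel_limit Optionally restrict to the first `pixel_limit` pixels.
#' @return List of [correlation_record()], one per complete window.
#' @export
correlate_frame_stream <- function(stream, window_length, n_delays = 16L,
                                   mode = c("raw", "onboard16"),
                                   pixel_limit = NULL) {
  mode <- match.arg(mode)
  if (mode == "onboard16") n_delays <- 16L
  dt <- stream$frame_period_s
  grid <- delay_grid(dt, n_delays)
  counts <- stream$counts
  if (!is.null(pixel_limit))
    counts <- counts[, seq_len(pixel_limit), drop = FALSE]
  spans_per_window <- curves_per_window(window_length, n_delays, dt)
  if (spans_per_window < 1) stop("window shorter than one curve span")
  curves <- pixel_window_g2(counts, n_delays, n_delays)  # per-span curves
  n_span <- dim(curves)[2]
  n_win <- n_span %/% spans_per_window
  lapply(seq_len(n_win), function(w) {
    span_idx <- ((w - 1L) * spans_per_window + 1L):(w * spans_per_window)
    cm <- matrix(curves[, span_idx, ], nrow = n_delays)
    frames <- ((span_idx[1] - 1L) * n_delays + 1L):(span_idx[length(span_idx)] * n_delays)
    average_g2(cm, grid,
               window_start = (span_idx[1] - 1L) * n_delays * dt,
               window_length = window_length,
               n_pixels = ncol(counts),
               mean_rate = mean(counts[frames, , drop = FALSE]))
  })
}

#' On-board 16-delay autocorrelator emulation
#'
#' Convenience wrapper for [correlate_frame_stream()] with the fixed 16-delay
#' grid of the on-board FPGA mode; numerically identical to
#' [compute_g2_pixel()] evaluated span by span on the 16-delay grid.
#'
#' @inheritParams correlate_frame_stream
#' @param timing Optional [sensor_timing()] consistency check
#'   (`mode = "onboard16"`).
#' @return List of [correlation_record()] on the 16-delay grid.
#' @export
onboard16_g2 <- function(stream, window_length, timing = NULL) {
  if (!is.null(timing) && timing$mode != "onboard16")
    stop("timing mode must be onboard16")
  correlate_frame_stream(stream, window_length, mode = "onboard16")
}
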