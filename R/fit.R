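#' Fit options for the semi-infinite g2 model
#'
#' @param preset `"custom"`, `"arm-raw"` (all nonzero delays of a 46-delay
#'   grid) or `"pfc-onboard"` (first 12 nonzero delays of the 16-delay
#'   on-board grid, the deep-channel setting in which later delays are too
#'   noisy).
#' @param beta_bounds Bounds for the correlation amplitude; default
#'   `c(0, 0.7)`.
#' @param bfi_bounds Positive BFI interval (cm^2/s); default
#'   `c(1e-12, 1e-5)`, a wide bracket around physiological values.
#' @param delay_subset Indices (into the nonzero delays) used for fitting;
#'   `NULL` means all nonzero delays. The tau = 0 bin is always excluded
#'   (shot-noise dominated).
#' @param offset_correction Apply [correct_g2_offset()] before fitting.
#' @param exclusion_threshold Trial-level median-residual threshold
#'   (default 0.03, strict `>` comparison).
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(preset = c("custom", "arm-raw", "pfc-onboard"),
                        beta_bounds = c(0, 0.7),
                        bfi_bounds = c(1e-12, 1e-5),
                        delay_subset = NULL,
                        offset_correction = TRUE,
                        exclusion_threshold = 0.03) {
  preset <- match.arg(preset)
  if (preset == "pfc-onboard") delay_subset <- 1:12
  if (preset == "arm-raw") delay_subset <- 1:45
  stopifnot(beta_bounds[1] < beta_bounds[2],
            bfi_bounds[1] > 0, bfi_bounds[1] < bfi_bounds[2])
  if (!is.null(delay_subset) && length(delay_subset) == 0)
    stop("delay_subset must be non-empty")
  structure(list(preset = preset, beta_bounds = beta_bounds,
                 bfi_bounds = bfi_bounds, delay_subset = delay_subset,
                 offset_correction = offset_correction,
                 exclusion_threshold = exclusion_threshold),
            class = "fit_options")
}

#' Analytic g2 model
#'
#' Semi-infinite correlation-diffusion g1 chained through the Siegert
#' relation: `g2(tau) = 1 + beta * g1(tau; bfi)^2`.
#'
#' @inheritParams g1_semi_infinite
#' @param beta Correlation amplitude.
#' @return g2 values at `delays`.
#' @export
model_g2 <- function(props, geom, bfi, beta, delays) {
  g2_from_g1(g1_semi_infinite(props, geom, bfi, delays), beta)
}

#' Tail-anchored additive offset correction of a measured g2 curve
#'
#' Short correlator integration windows bias the g2 estimate by a roughly
#' additive offset. The correction shifts the curve so the mean over the last
#' quartile of delays (which should be fully decorrelated) equals 1. If the
#' curve has visibly not decayed there (tail mean above `1 + beta_hat/2`,
#' with `beta_hat` read off the first nonzero delay), the correction is
#' skipped with a warning.
#'
#' @param record A [correlation_record()] with at least 3 tail delays beyond
#'   the expected decorrelation.
#' @return The corrected record; the applied offset is stored in
#'   `record$offset_applied`.
#' @export
correct_g2_offset <- function(record) {
  stopifnot(inherits(record, "correlation_record"))
  nz <- which(record$grid$delays > 0)
  if (length(nz) < 6) stop("need >= 6 nonzero delays for a tail estimate")
  n_tail <- max(3L, floor(length(nz) / 4))
  tail_idx <- nz[(length(nz) - n_tail + 1L):length(nz)]
  tail_mean <- mean(record$g2[tail_idx])
  beta_hat <- max(record$g2[nz[1]] - 1, 0)
  if (tail_mean > 1 + beta_hat / 2) {
    warning("g2 tail still decaying; offset correction skipped")
    record$offset_applied <- 0
    return(record)
  }
  offset <- 1 - tail_mean
  record$g2 <- record$g2 + offset
  record$offset_applied <- offset
  record
}

#' Fit BFI and beta to a measured correlation record
#'
#' Bounded Levenberg-Marquardt least squares of [model_g2()] against the
#' measured curve on the selected nonzero-delay subset. BFI is optimized on a
#' log10 scale between its bounds; beta within `beta_bounds`. The start point
#' is fixed (beta = 0.25, BFI = 1e-8 cm^2/s) with three deterministic
#' alternative starts on non-convergence, so results are reproducible.
#'
#' @param record A [correlation_record()].
#' @param props [optical_properties()].
#' @param geom [probe_geometry()].
#' @param options [fit_options()].
#' @return A `bfi_sample`: list with `time`, `bfi`, `beta`, `residual`
#'   (RMS of model minus data over the fitted delays), `valid`.
#' @export
fit_bfi <- function(record, props, geom, options = fit_options()) {
  stopifnot(inherits(record, "correlation_record"))
  if (any(!is.finite(record$g2)))
    return(structure(list(time = record$window_start, bfi = NA_real_,
                          beta = NA_real_, residual = Inf, valid = FALSE),
                     class = "bfi_sample"))
  if (options$offset_correction)
    record <- suppressWarnings(correct_g2_offset(record))
  nz <- which(record$grid$delays > 0)
  idx <- if (is.null(options$delay_subset)) nz else nz[options$delay_subset]
  if (any(is.na(idx)) || !length(idx)) stop("delay subset not present in record")
  tau <- record$grid$delays[idx]
  y <- record$g2[idx]
  lb <- log10(options$bfi_bounds)
  resid_fn <- function(par) {
    model_g2(props, geom, 10^par[1], par[2], tau) - y
  }
  starts <- list(c(-8, 0.25), c(-9, 0.1), c(-7, 0.5), c(-10, 0.25))
  starts <- lapply(starts, function(s)
    c(min(max(s[1], lb[1]), lb[2]),
      min(max(s[2], options$beta_bounds[1]), options$beta_bounds[2])))
  fit <- NULL
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = c(lb[1], options$beta_bounds[1]),
                         upper = c(lb[2], options$beta_bounds[2]),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(f) && f$info %in% 1:4) { fit <- f; break }
  }
  if (is.null(fit))
    return(structure(list(time = record$window_start, bfi = NA_real_,
                          beta = NA_real_, residual = Inf, valid = FALSE),
                     class = "bfi_sample"))
  bfi <- 10^fit$par[1]
  beta <- fit$par[2]
  rms <- sqrt(mean(resid_fn(fit$par)^2))
  # beta collapsing to its lower bound means the curve carried no speckle
  # decay and BFI is unidentifiable
  valid <- beta > 1e-4
  structure(list(time = record$window_start, bfi = bfi, beta = beta,
                 residual = rms, valid = valid),
            class = "bfi_sample")
}

#' Fit a time series of correlation records into a BFI trace
#'
#' @param records List of uniformly spaced [correlation_record()]s.
#' @param props,geom,options As in [fit_bfi()].
#' @param segment_label Optional label (`control_before`, `test`,
#'   `control_after`).
#' @return A `bfi_trace` with columns `time`, `bfi`, `beta`, `residual`,
#'   `valid`, and `sample_rate = 1 / Delta-T`.
#' @export
trace_from_records <- function(records, props, geom,
                               options = fit_options(),
                               segment_label = NA_character_) {
  if (!length(records)) stop("empty record list")
  starts <- vapply(records, `[[`, numeric(1), "window_start")
  dt <- records[[1]]$window_length
  if (length(starts) > 1) {
    gaps <- which(abs(diff(starts) - dt) > 1e-9 * max(dt, 1))
    if (length(gaps))
      stop("records not uniformly spaced; gaps after windows at t = ",
           paste(signif(starts[gaps], 6), collapse = ", "))
  }
  fits <- lapply(records, fit_bfi, props = props, geom = geom,
                 options = options)
  trace <- data.frame(
    time = starts,
    bfi = vapply(fits, `[[`, numeric(1), "bfi"),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    residual = vapply(fits, `[[`, numeric(1), "residual"),
    valid = vapply(fits, `[[`, logical(1), "valid"))
  attr(trace, "sample_rate") <- 1 / dt
  attr(trace, "segment_label") <- segment_label
  class(trace) <- c("bfi_trace", "data.frame")
  trace
}

#' Trial-level exclusion on the median fit residual
#'
#' A trial is excluded iff the median of its per-window RMS fit residuals,
#' across all samples of all its traces, exceeds the threshold (strictly;
#' trials exactly at the threshold are kept).
#'
#' @param trials Named list; each element is one trial, either a single
#'   `bfi_trace` or a list of segment traces carrying `residual` columns.
#' @param threshold Median-residual threshold (default 0.03).
#' @return List with `kept`, `excluded` (names) and a `summary` data.frame of
#'   per-trial median residuals and decisions.
#' @export
exclude_trials <- function(trials, threshold = 0.03) {
  med <- vapply(trials, function(tr) {
    if (is.data.frame(tr)) tr <- list(tr)
    stats::median(unlist(lapply(tr, function(seg) seg$residual)), na.rm = TRUE)
  }, numeric(1))
  # strict comparison with a tie guard so medians exactly at the threshold
  # (up to floating-point representation) are kept
  excluded <- med - threshold > 1e-12
  summary <- data.frame(trial = names(trials), median_residual = med,
                        excluded = excluded, row.names = NULL)
  list(kept = names(trials)[!excluded], excluded = names(trials)[excluded],
       summary = summary)
}

#' Initial g2 slope as a simplified blood-flow metric
#'
#' Ordinary least-squares slope of g2 versus tau over the first
#' `n_delays_used` nonzero delays; negative for decaying curves and larger in
#' magnitude for faster flow.
#'
#' @param record A [correlation_record()].
#' @param n_delays_used Number of initial nonzero delays (>= 2).
#' @return Slope in 1/s.
#' @export
early_slope_metric <- function(record, n_delays_used = 5) {
  nz <- which(record$grid$delays > 0)
  if (length(nz) < 2 || n_delays_used < 2)
    stop("need at least 2 nonzero delays")
  idx <- nz[seq_len(min(n_delays_used, length(nz)))]
  tau <- record$grid$delays[idx]
  y <- record$g2[idx]
  sum((tau - mean(tau)) * (y - mean(y))) / sum((tau - mean(tau))^2)
}
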