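#' Detector simulation parameters
#'
#' @param n_pixels Number of simulated independent speckle pixels M.
#' @param exposure Per-frame exposure (s); the frame period equals the
#'   exposure (frames are taken as contiguous).
#' @param n_frames Frames per simulation when the BFI trace is static
#'   (single-sample); for pulsatile traces the frame count follows from the
#'   trace length and `frames_per_sample`.
#' @param coherent_fraction Fraction f of the detected intensity carried by
#'   the dynamic speckle, in `[0, 1]`. For a single polarization mode the
#'   realized correlation amplitude is `beta = f^2`, so the study's measured
#'   beta of 0.15-0.3 corresponds to f of about 0.39-0.55.
#' @param mean_rate Mean photon detections per pixel per frame (< 1).
#' @param dark_rate Dark-count probability per frame.
#' @param seed Integer seed; identical seeds give bit-identical streams.
#' @param max_elements Memory budget: refuse simulations with more than this
#'   many frame-pixel elements (chunk the request instead).
#' @return An object of class `detector_sim_params`.
#' @export
detector_sim_params <- function(n_pixels = 1024, exposure = 3e-6,
                                n_frames = 10000, coherent_fraction = 0.5,
                                mean_rate = 0.05, dark_rate = 1e-4,
                                seed = 1L, max_elements = 2.5e8) {
  if (n_pixels < 1) stop("n_pixels must be >= 1")
  if (coherent_fraction < 0 || coherent_fraction > 1)
    stop("coherent_fraction must lie in [0, 1]")
  total <- mean_rate + dark_rate
  if (total <= 0 || total >= 1)
    stop("mean_rate + dark_rate must lie in (0, 1)")
  structure(list(n_pixels = as.integer(n_pixels), exposure = exposure,
                 n_frames = as.integer(n_frames),
                 coherent_fraction = coherent_fraction,
                 mean_rate = mean_rate, dark_rate = dark_rate,
                 seed = as.integer(seed), max_elements = max_elements),
            class = "detector_sim_params")
}

# Calibrate the per-frame interaction rate r so that the expected event
# probability E[1 - exp(-(r*I + d0))] equals mean_rate + dark_rate, where
# I = f*X + (1-f) with X ~ Exp(1) (unit-mean speckle intensity) and
# d0 = -log(1 - dark_rate). Uses the closed-form Laplace transform
# E[exp(-r I)] = exp(-r(1-f)) / (1 + r f).
.calibrate_rate <- function(mean_rate, dark_rate, f) {
  if (mean_rate == 0) return(0)
  target <- (1 - mean_rate - dark_rate) / (1 - dark_rate)
  fn <- function(r) exp(-r * (1 - f)) / (1 + r * f) - target
  stats::uniroot(fn, c(0, 60), tol = 1e-14)$root
}

# Circulant-embedding eigenvalues for a stationary complex Gaussian field with
# target autocorrelation rho(k) = g1(k * dt), k = 0..n_pad/2.
.field_eigenvalues <- function(props, geom, bfi, dt, n_pad) {
  half <- n_pad / 2
  rho <- g1_semi_infinite(props, geom, bfi, (0:half) * dt)
  cvec <- c(rho, rev(rho[2:half]))
  pmax(Re(stats::fft(cvec)), 0)
}

#' Simulate binary SPAD-array photon streams
#'
#' For each pixel an independent circular complex Gaussian speckle field is
#' synthesized by spectral shaping (white noise filtered so its
#' autocorrelation equals the semi-infinite-model g1 at the window-local BFI;
#' exact second-order statistics, O(T log T) per pixel). The BFI is held
#' constant within each waveform sample of `bfi_trace` (piecewise-stationary).
#' The detected intensity mixes the speckle with a static background,
#' `I = f |E|^2 + (1 - f)`, and a binary event is drawn per frame with
#' probability `1 - exp(-(r I + d0))`, where the interaction rate r is
#' calibrated so the mean event rate equals `mean_rate + dark_rate`.
#'
#' @param props [optical_properties()].
#' @param geom [probe_geometry()].
#' @param bfi_trace A `bfi_trace` (possibly a single-row static trace, see
#'   [bfi_trace()]), giving the ground-truth BFI per waveform sample.
#' @param det [detector_sim_params()].
#' @param frames_per_sample Frames simulated per waveform sample. Defaults to
#'   `round(1 / (sample_rate * exposure))` (the physically contiguous count)
#'   for multi-sample traces and to `det$n_frames` for static traces. Smaller
#'   values down-sample the stream for desk-scale runs.
#' @return A `frame_stream`: list with integer matrix `counts`
#'   (frames x pixels), timing attributes and the ground-truth inputs.
#' @export
simulate_speckle_photons <- function(props, geom, bfi_trace, det,
                                     frames_per_sample = NULL) {
  stopifnot(inherits(det, "detector_sim_params"))
  if (is.numeric(bfi_trace) && length(bfi_trace) == 1)
    bfi_trace <- data.frame(time = 0, bfi = bfi_trace, valid = TRUE)
  n_samp <- nrow(bfi_trace)
  if (is.null(frames_per_sample)) {
    if (n_samp == 1) {
      frames_per_sample <- det$n_frames
    } else {
      sr <- attr(bfi_trace, "sample_rate")
      if (is.null(sr)) stop("bfi_trace needs a sample_rate attribute")
      frames_per_sample <- max(1L, round(1 / (sr * det$exposure)))
    }
  }
  n_frames <- n_samp * frames_per_sample
  if (as.double(n_frames) * det$n_pixels > det$max_elements)
    stop("requested ", n_frames, " frames x ", det$n_pixels,
         " pixels exceeds the memory budget (max_elements = ",
         format(det$max_elements, scientific = TRUE),
         "); simulate in chunks of pixels or windows and combine")
  f <- det$coherent_fraction
  r_cal <- .calibrate_rate(det$mean_rate, det$dark_rate, f)
  d0 <- -log(1 - det$dark_rate)
  L <- frames_per_sample
  n_pad <- stats::nextn(max(2L * L, 16L), 2)
  counts <- matrix(0L, n_frames, det$n_pixels)
  chunk <- max(1L, min(det$n_pixels, floor(1.6e7 / n_pad)))
  starts <- seq.int(1L, det$n_pixels, by = chunk)
  with_seed(det$seed, {
    for (s in seq_len(n_samp)) {
      lam <- if (f > 0)
        .field_eigenvalues(props, geom, bfi_trace$bfi[s], det$exposure, n_pad)
      rows <- ((s - 1L) * L + 1L):(s * L)
      for (p0 in starts) {
        nc <- min(chunk, det$n_pixels - p0 + 1L)
        if (f > 0) {
          w <- matrix(complex(real = stats::rnorm(n_pad * nc),
                              imaginary = stats::rnorm(n_pad * nc)),
                      n_pad, nc) / sqrt(2)
          e <- stats::mvfft(w * sqrt(lam)) / sqrt(n_pad)
          intensity <- f * Mod(e[seq_len(L), , drop = FALSE])^2 + (1 - f)
        } else {
          intensity <- matrix(1, L, nc)
        }
        p_ev <- 1 - exp(-(r_cal * intensity + d0))
        ev <- matrix(stats::runif(L * nc), L, nc) < p_ev
        counts[rows, p0:(p0 + nc - 1L)] <- ev
      }
    }
  })
  structure(list(counts = counts,
                 exposure_s = det$exposure,
                 frame_period_s = det$exposure,
                 n_frames = n_frames, n_pixels = det$n_pixels,
                 frames_per_sample = frames_per_sample,
                 sds_cm = geom$sds,
                 wavelength_nm = props$wavelength,
                 seed = det$seed,
                 det = det, props = props, geom = geom,
                 bfi_trace = bfi_trace),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat("frame_stream:", x$n_frames, "frames x", x$n_pixels, "pixels\n")
  cat("  exposure", format(x$exposure_s), "s, SDS", x$sds_cm,
      "cm, mean rate", round(mean(x$counts), 5), "events/frame\n")
  invisible(x)
}

#' Write / read a frame stream as plain text
#'
#' The photon counts are stored as CSV (frames x pixels), all metadata in a
#' JSON sidecar, and the ground-truth BFI trace as CSV
#' (`time_s, bfi_cm2_per_s`).
#'
#' @param stream A `frame_stream`.
#' @param dir Output directory (created if missing).
#' @return `write_frame_stream` returns `dir` invisibly; `read_frame_stream`
#'   returns the reconstructed `frame_stream` (counts and metadata; model
#'   objects are restored from the sidecar fields).
#' @export
write_frame_stream <- function(stream, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(stream$counts),
                     file.path(dir, "counts.csv"))
  meta <- stream[c("exposure_s", "frame_period_s", "n_frames", "n_pixels",
                   "frames_per_sample", "sds_cm", "wavelength_nm", "seed")]
  meta$det <- unclass(stream$det)
  meta$props <- unclass(stream$props)
  meta$geom <- unclass(stream$geom)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- data.frame(time_s = stream$bfi_trace$time,
                      bfi_cm2_per_s = stream$bfi_trace$bfi)
  data.table::fwrite(truth, file.path(dir, "truth_bfi.csv"))
  invisible(dir)
}

#' @rdname write_frame_stream
#' @export
read_frame_stream <- function(dir) {
  counts <- as.matrix(data.table::fread(file.path(dir, "counts.csv")))
  dimnames(counts) <- NULL
  storage.mode(counts) <- "integer"
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  truth <- data.table::fread(file.path(dir, "truth_bfi.csv"))
  props <- do.call(optical_properties,
                   meta$props[c("mu_a", "mu_s_prime", "n_tissue", "n_outside",
                                "wavelength")])
  geom <- do.call(probe_geometry,
                  meta$geom[c("sds", "fiber_diameter", "pixel_active_diameter",
                              "fiber_sensor_distance", "source_radius",
                              "source_power")])
  det <- do.call(detector_sim_params,
                 meta$det[c("n_pixels", "exposure", "n_frames",
                            "coherent_fraction", "mean_rate", "dark_rate",
                            "seed", "max_elements")])
  structure(list(counts = counts, exposure_s = meta$exposure_s,
                 frame_period_s = meta$frame_period_s,
                 n_frames = meta$n_frames, n_pixels = meta$n_pixels,
                 frames_per_sample = meta$frames_per_sample,
                 sds_cm = meta$sds_cm, wavelength_nm = meta$wavelength_nm,
                 seed = meta$seed, det = det, props = props, geom = geom,
                 bfi_trace = data.frame(time = truth$time_s,
                                        bfi = truth$bfi_cm2_per_s,
                                        valid = TRUE)),
            class = "frame_stream")
}
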