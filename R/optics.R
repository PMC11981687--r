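#' Optical properties of the probed tissue
#'
#' Bundles the homogeneous-tissue optical parameters used by the semi-infinite
#' correlation-diffusion model. The in-medium wavenumber
#' `k0 = 2 * pi * n_tissue / lambda` (in 1/cm) is derived on construction.
#' Defaults are literature-typical values for adult tissue at 785 nm; they are
#' assumptions to be overridden per study, never ground truth.
#'
#' @param mu_a Absorption coefficient (1/cm).
#' @param mu_s_prime Reduced scattering coefficient (1/cm).
#' @param n_tissue Refractive index of the tissue (dimensionless).
#' @param n_outside Refractive index of the exterior medium (dimensionless).
#' @param wavelength Laser wavelength (nm).
#' @return An object of class `optical_properties`.
#' @export
#' @examples
#' op <- optical_properties()
#' op$k0
optical_properties <- function(mu_a = 0.17, mu_s_prime = 8, n_tissue = 1.4,
                               n_outside = 1.0, wavelength = 785) {
  if (!all(c(mu_a, mu_s_prime, n_tissue, n_outside, wavelength) > 0))
    stop("all optical properties must be positive")
  if (mu_s_prime <= mu_a)
    stop("mu_s_prime must exceed mu_a for the diffusion approximation")
  wavelength_cm <- wavelength * 1e-7
  structure(list(
    mu_a = mu_a, mu_s_prime = mu_s_prime,
    n_tissue = n_tissue, n_outside = n_outside,
    wavelength = wavelength,
    k0 = 2 * pi * n_tissue / wavelength_cm
  ), class = "optical_properties")
}

#' Probe geometry of a PDCS detection channel
#'
#' @param sds Source-detector separation rho on the skin (cm).
#' @param fiber_diameter Detection fiber core diameter D (um).
#' @param pixel_active_diameter Active-area diameter of one SPAD pixel (um).
#' @param fiber_sensor_distance Fiber-tip-to-sensor distance z (mm). If `NULL`
#'   it is set to the speckle-matched distance [speckle_spot_distance()] for
#'   `wavelength` so that one speckle covers one pixel active area.
#' @param source_radius Illumination spot radius on the skin (mm).
#' @param source_power Laser power (mW).
#' @param wavelength Wavelength used for speckle matching (nm).
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(sds = 1.5, fiber_diameter = 200,
                           pixel_active_diameter = 6.9,
                           fiber_sensor_distance = NULL,
                           source_radius = 4, source_power = 100,
                           wavelength = 785) {
  if (sds <= 0) stop("sds must be positive")
  if (is.null(fiber_sensor_distance))
    fiber_sensor_distance <- speckle_spot_distance(
      wavelength, fiber_diameter, pixel_active_diameter)
  structure(list(
    sds = sds, fiber_diameter = fiber_diameter,
    pixel_active_diameter = pixel_active_diameter,
    fiber_sensor_distance = fiber_sensor_distance,
    source_radius = source_radius, source_power = source_power
  ), class = "probe_geometry")
}

#' Speckle-matched fiber-to-sensor distance
#'
#' The far-field speckle grain diameter at distance z behind a fiber of core
#' diameter D is d = lambda * z / D. To match a target speckle diameter d
#' (typically the SPAD pixel active-area diameter) the sensor is placed at
#' z = d * D / lambda.
#'
#' @param wavelength Wavelength (nm).
#' @param fiber_diameter Fiber core diameter D (um).
#' @param target_speckle_diameter Desired speckle diameter d (um).
#' @return Fiber-to-sensor distance z in mm.
#' @export
#' @examples
#' speckle_spot_distance(785, 200, 6.9)   # ~1.76 mm
#' speckle_spot_distance(785, 1500, 6)    # ~11.5 mm
speckle_spot_distance <- function(wavelength, fiber_diameter,
                                  target_speckle_diameter) {
  if (!all(c(wavelength, fiber_diameter, target_speckle_diameter) > 0))
    stop("all inputs must be positive")
  z_m <- (target_speckle_diameter * 1e-6) * (fiber_diameter * 1e-6) /
    (wavelength * 1e-9)
  z_m * 1e3
}

#' Irradiance of the illumination spot
#'
#' Average irradiance of `power_mw` spread over a disc of radius `radius_mm`,
#' for comparison against the maximum permissible exposure (MPE) for skin
#' at near-infrared wavelengths, 300 mW/cm^2.
#'
#' @param power_mw Laser power (mW).
#' @param radius_mm Illumination spot radius (mm).
#' @return Irradiance in mW/cm^2.
#' @export
#' @examples
#' beam_irradiance(100, 4)  # < 300 mW/cm^2
beam_irradiance <- function(power_mw, radius_mm) {
  if (power_mw < 0 || radius_mm <= 0) stop("invalid power or radius")
  power_mw / (pi * (radius_mm / 10)^2)
}

#' @rdname beam_irradiance
#' @param mpe_limit MPE limit in mW/cm^2 (default 300).
#' @export
mpe_compliant <- function(power_mw, radius_mm, mpe_limit = 300) {
  beam_irradiance(power_mw, radius_mm) <= mpe_limit
}

# Effective reflection coefficient for the refractive-index mismatch at the
# tissue boundary (standard polynomial approximation in the index ratio).
effective_reflection <- function(n_tissue, n_outside) {
  n <- n_tissue / n_outside
  -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
}

#' Semi-infinite correlation-diffusion field autocorrelation g1
#'
#' Closed-form extrapolated-zero-boundary Green's-function solution of the
#' correlation diffusion equation for a homogeneous half-space, with red blood
#' cell motion modelled as effective Brownian diffusion with coefficient `bfi`:
#'
#' \deqn{G_1(\rho,\tau) \propto \frac{e^{-K(\tau) r_1}}{r_1} -
#'   \frac{e^{-K(\tau) r_b}}{r_b}}
#'
#' with \eqn{K(\tau) = \sqrt{3\mu_a\mu_s' + 6\mu_s'^2 k_0^2 \, BFI \, \tau}},
#' \eqn{r_1 = \sqrt{\rho^2 + z_0^2}}, \eqn{r_b = \sqrt{\rho^2 + (z_0+2z_b)^2}},
#' \eqn{z_0 = 1/\mu_s'} and the extrapolation length \eqn{z_b} from the
#' effective-reflection coefficient. The result is normalized so g1(0) = 1.
#'
#' @param props [optical_properties()].
#' @param geom [probe_geometry()]; only `sds` is used.
#' @param bfi Blood flow index (cm^2/s), >= 0.
#' @param delays Non-negative, ascending delay times (s).
#' @return Numeric vector of g1 values in (0, 1].
#' @export
g1_semi_infinite <- function(props, geom, bfi, delays) {
  stopifnot(inherits(props, "optical_properties"))
  if (bfi < 0) stop("bfi must be non-negative")
  if (any(delays < 0)) stop("delays must be non-negative")
  if (is.unsorted(delays)) stop("delays must be ascending")
  rho <- if (inherits(geom, "probe_geometry")) geom$sds else as.numeric(geom)
  mu_a <- props$mu_a; mu_sp <- props$mu_s_prime; k0 <- props$k0
  z0 <- 1 / mu_sp
  reff <- effective_reflection(props$n_tissue, props$n_outside)
  zb <- 2 * (1 + reff) / (3 * mu_sp * (1 - reff))
  r1 <- sqrt(rho^2 + z0^2)
  rb <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  g1_of <- function(tau) {
    k <- sqrt(3 * mu_a * mu_sp + 6 * mu_sp^2 * k0^2 * bfi * tau)
    exp(-k * r1) / r1 - exp(-k * rb) / rb
  }
  g1_of(delays) / g1_of(0)
}

#' Siegert relation: intensity autocorrelation from field autocorrelation
#'
#' `g2 = 1 + beta * |g1|^2`, where beta is the correlation amplitude
#' (coherence factor), `g2(0) - 1`.
#'
#' @param g1 Field autocorrelation values in `[0, 1]`.
#' @param beta Correlation amplitude in `[0, 1]`.
#' @return g2 values.
#' @export
#' @examples
#' g2_from_g1(c(1, 0.5, 0), 0.2)
g2_from_g1 <- function(g1, beta) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  1 + beta * Mod(g1)^2
}
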