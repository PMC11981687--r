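# pdcs — parallelized diffuse correlation spectroscopy, simulated and analyzed

Diffuse correlation spectroscopy (DCS) measures microvascular blood flow by
tracking how fast the speckle pattern of multiply scattered coherent light
decorrelates. Its Achilles heel is signal-to-noise: at the source–detector
separations (SDS ≈ 4 cm) needed to reach the adult brain through scalp and
skull, photon rates collapse. Parallelized DCS (PDCS) answers with SPAD
arrays — hundreds to hundreds of thousands of single-photon pixels, each
watching one speckle — and averages all per-pixel autocorrelations, cutting
the noise of the averaged estimate by √M.

This package implements that pipeline end to end, for researchers in diffuse
optics and biomedical engineering who want a tested, fully synthetic-data-
verifiable reference implementation:

- **Forward model.** Semi-infinite correlation-diffusion field
  autocorrelation with extrapolated-zero boundary,
  g₁(τ) ∝ e^(−K(τ)r₁)/r₁ − e^(−K(τ)r_b)/r_b with
  K(τ) = √(3μₐμₛ′ + 6μₛ′²k₀²·BFI·τ), chained through the Siegert relation
  g₂ = 1 + β|g₁|², where BFI (cm²/s) is the blood flow index and β the
  coherence factor (`g1_semi_infinite()`, `g2_from_g1()`, `model_g2()`).
- **Synthetic SPAD streams.** Per-pixel circular complex Gaussian speckle
  fields with exactly the model autocorrelation (spectral shaping), mixed
  with a static background (β = coherent_fraction²) and binarized with a
  calibrated detection probability; pulsatile ground-truth BFI waveforms
  with systolic peak, dicrotic notch, diastolic peak and diastolic end
  markers (`simulate_speckle_photons()`, `make_pulsatile_bfi()`).
- **Correlator.** The lag-shrinking g₂(τ) estimator per pixel, sub-window
  and pixel averaging that reproduces the published curves-per-window
  arithmetic, and the on-board 16-delay FPGA mode
  (`compute_g2_pixel()`, `correlate_frame_stream()`, `onboard16_g2()`).
- **BFI fitting.** Bounded Levenberg–Marquardt over (log₁₀BFI, β) with
  β ∈ [0, 0.7], tail-anchored offset correction for short-window g₂ bias,
  RMS residuals and the median-residual > 0.03 trial exclusion rule
  (`fit_bfi()`, `correct_g2_offset()`, `exclude_trials()`).
- **Pulse analysis.** Spectral pulse-rate estimation gated to 0.33–2.65 Hz,
  SP/DE/DN/DP marker detection, and the pulsatility index
  PI = (⟨BFI⟩_SP − ⟨BFI⟩_DE)/⟨BFI⟩ (`estimate_pulse_rate()`,
  `detect_markers()`, `pulsatility_index()`).
- **Noise model.** Marker-conditioned g₂ noise N̄ = ⟨std(g₂(τ))⟩_τ across
  equivalent pulse phases, and the noise-versus-pixel-count scaling that
  verifies the √M law (`g2_noise_at_markers()`, `noise_vs_pixels()`).
- **Group statistics.** Trial normalization to 100% of the first control
  median, per-condition summaries, Cohen's d, and the mixed model
  rBFI ~ Trial + Condition + (Condition | Subject) via lme4/lmerTest
  (`normalize_trial()`, `lme_contrast()`, `condition_summary()`).

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` … `05_group_stats.R`) that run a complete synthetic study —
optical design numbers, photon streams, correlation, fitting, pulse and
noise analysis, group contrasts — writing tables under `results/`.

## Worked example

Simulate a 1024-pixel SPAD stream at the deep channel (SDS 4 cm, 3.37 µs
exposure) with a known BFI of 1e-8 cm²/s and β = 0.25, average g₂ over all
pixels in four windows, and fit the model:

```r
library(pdcs)
props <- optical_properties()        # mu_a 0.17 /cm, mu_s' 8 /cm, 785 nm
geom  <- probe_geometry(sds = 4, fiber_diameter = 1500,
                        pixel_active_diameter = 6)

det <- detector_sim_params(n_pixels = 1024, exposure = 3.37e-6,
                           n_frames = 16000, coherent_fraction = 0.5,
                           mean_rate = 0.05, seed = 1)
stream <- simulate_speckle_photons(props, geom, 1e-8, det)

grid <- delay_grid(3.37e-6, 16)
g2a  <- pixel_window_g2(stream, 16, 4000)
recs <- lapply(1:4, function(w)
  correlation_record((w - 1) * 4000 * 3.37e-6, 4000 * 3.37e-6,
                     rowMeans(g2a[, w, ]), grid, 1024L, 1L))
trace <- trace_from_records(recs, props, geom,
                            fit_options(preset = "pfc-onboard"))
data.frame(time_s = round(trace$time, 4),
           bfi_cm2_per_s = signif(trace$bfi, 3),
           beta = round(trace$beta, 3),
           residual = signif(trace$residual, 2))
#>   time_s bfi_cm2_per_s  beta residual
#> 1 0.0000      1.28e-08 0.256   0.0110
#> 2 0.0135      9.66e-09 0.219   0.0086
#> 3 0.0270      9.98e-09 0.224   0.0100
#> 4 0.0404      9.49e-09 0.221   0.0110
```

The fitted BFI scatters around the simulated 1e-8 cm²/s; the fitted β sits
slightly below the nominal 0.25 because binarizing photon counts compresses
the measured correlation amplitude (the effect is absorbed by β and leaves
the BFI essentially unbiased — see the methods vignette). The residual
column is the RMS misfit used by the trial exclusion rule; all values here
are far below the 0.03 threshold.

Optical design helpers reproduce the hardware numbers directly:

```r
speckle_spot_distance(785, 200, 6.9)   # 1.758 mm fiber-sensor distance
speckle_spot_distance(785, 1500, 6)    # 11.465 mm
exposure_time(250, 1)                  # 1e-05 s  (10 us)
curves_per_window(0.125, 56, 3e-6)     # 744 curves per averaging window
beam_irradiance(100, 4)                # 199 mW/cm^2, below the 300 MPE
```

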