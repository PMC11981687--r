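---
title: "Methods: simulating and analyzing massively parallelized DCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing massively parallelized DCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcs)
```

## The measurement and its model

Diffuse correlation spectroscopy (DCS) illuminates tissue with a coherent
near-infrared laser and detects multiply scattered light at a source-detector
separation (SDS) $\rho$ on the skin. Red-blood-cell motion decorrelates the
detected speckle; the decay rate of the normalized intensity autocorrelation

$$g_2(\tau) = \frac{\langle I(t)\, I(t+\tau)\rangle}{\langle I(t)\rangle^2}$$

encodes a blood flow index (BFI), the effective Brownian diffusion
coefficient of the scatterers in cm²/s. Parallelized DCS (PDCS) replaces the
single photon counter with a SPAD array in which every pixel samples one
speckle: averaging $M$ independent per-pixel estimates reduces the noise of
the averaged $g_2$ by $\sqrt{M}$, which is what makes large SDS (deep,
cerebral) measurements feasible at 8–10 Hz BFI sampling.

The analytic forward model chains two standard results:

1. **Semi-infinite correlation diffusion.** The field autocorrelation for a
   homogeneous half-space with an extrapolated-zero boundary is
   $$G_1(\rho,\tau) \propto \frac{e^{-K(\tau) r_1}}{r_1} -
     \frac{e^{-K(\tau) r_b}}{r_b}, \qquad
     K(\tau) = \sqrt{3\mu_a\mu_s' + 6\mu_s'^2 k_0^2\,\mathrm{BFI}\,\tau},$$
   with $r_1 = \sqrt{\rho^2 + z_0^2}$, $r_b = \sqrt{\rho^2+(z_0+2z_b)^2}$,
   $z_0 = 1/\mu_s'$, and $z_b$ from the effective-reflection polynomial in
   the tissue/air index ratio. `g1_semi_infinite()` normalizes so
   $g_1(0)=1$. This closed form is the standard semi-infinite solution used
   throughout the DCS literature; a second, independent transcription of it
   serves as a unit-test oracle.
2. **Siegert relation.** `g2_from_g1()` maps the field to intensity
   correlation, $g_2 = 1 + \beta |g_1|^2$, with $\beta$ the coherence
   factor set by speckle-to-pixel matching and the unpolarized/static light
   fraction.

Default optical properties are literature-typical assumptions for adult
tissue at 785 nm ($\mu_a = 0.17$ cm⁻¹, $\mu_s' = 8$ cm⁻¹, $n = 1.4$), fully
configurable and never treated as ground truth. Mismatches translate into
errors of the *absolute* BFI only; all group-level analysis uses relative
(normalized) BFI, which is insensitive to them.

## What the synthetic-data generator emulates

No raw study data are deposited, so every pipeline stage is validated
against `simulate_speckle_photons()`, which produces binary SPAD frame
streams with controlled statistics:

- **Speckle fields.** Each pixel carries an independent circular complex
  Gaussian process whose autocorrelation equals the semi-infinite $g_1$ at
  the pixel's current BFI. Fields are synthesized by spectral shaping
  (circulant embedding): white complex Gaussian noise is filtered with the
  square root of the discrete spectrum of the target autocorrelation, which
  gives exact second-order statistics in $O(T\log T)$ per pixel. Negative
  circulant eigenvalues (possible when the correlation has not decayed
  within half the embedding length) are clipped to zero; the affected mass
  is negligible for all configurations used here.
- **Coherence factor.** The detected intensity mixes the dynamic speckle
  with a static background, $I = f|E|^2 + (1-f)$, so a single polarization
  mode realizes $\beta = f^2$. The study's measured $\beta$ of 0.15–0.3
  corresponds to $f \approx 0.39\text{–}0.55$; the simulations here use
  $f = 0.5$, i.e. $\beta = 0.25$.
- **Binary detection.** A pixel fires in a frame with probability
  $1-\exp(-(rI + d_0))$, $d_0$ the dark-count term. The interaction rate
  $r$ is calibrated by root finding so the expected event rate equals the
  configured `mean_rate + dark_rate` exactly under the exponential
  intensity distribution. Binarization slightly compresses the measured
  correlation amplitude (in the end-to-end simulations the recovered
  $\beta$ sits a few hundredths below the nominal 0.25, shrinking as the
  event rate drops); the compression acts almost entirely on the fitted
  $\beta$ and leaves the fitted BFI essentially unbiased, which the fit
  tests verify.
- **Pulsatility.** `make_pulsatile_bfi()` builds a cardiac cycle from
  half-cosine segments — systolic upstroke to SP, fall to the dicrotic
  notch DN, rebound to the diastolic peak DP, decay to the diastolic end
  DE — with seeded cycle-period jitter. The notch anchor is clamped to 35%
  of the cycle so the template stays coherent at fast rates. Ground-truth
  marker locations (the extrema of the generated samples) ride along with
  the trace for closed-loop recall tests. The BFI is held constant within
  each waveform sample (piecewise-stationary); waveform samples are two
  orders of magnitude longer than the speckle decorrelation time, so the
  within-window nonstationarity is negligible.

The generator deliberately omits rolling-shutter row phases, afterpulsing
and cross-talk, spatial correlation between pixels, and photon time
tagging. Passing tests therefore demonstrate correctness of the estimators
and fitting chain under the stated statistical model, not robustness to
those hardware artifacts.

## The correlator

`compute_g2_pixel()` implements the lag-shrinking estimator: the numerator
averages all frame pairs that fit inside the window and the denominator is
the squared window mean. A brute-force double-loop oracle checks it exactly
on streams up to 1,000 frames. `correlate_frame_stream()` reproduces the
study's averaging scheme: an averaging window $\Delta T$ is partitioned
into consecutive spans of `n_delays` frames, one curve per span per pixel,
and all valid curves are averaged (pixels with zero counts in a span are
dropped and counted in the record's provenance). This arithmetic reproduces
the published curves-per-window counts (198, 201, 744) exactly; the
on-board mode fixes 16 delays with $\tau_{max}$ at 15 exposure times. The
fourth published count (2295) depends on an unpublished sensor overhead, so
the effective frame period remains a free parameter rather than a
hard-coded constant.

The $\tau = 0$ bin of binary counts is shot-noise dominated
($g_2(0) \approx 1/\text{rate}$) and is excluded from fitting and noise
averaging throughout.

## BFI fitting

`fit_bfi()` runs bounded Levenberg–Marquardt least squares of the analytic
$g_2$ against a measured record over a nonzero-delay subset, optimizing
$\log_{10}\mathrm{BFI}$ in $[10^{-12}, 10^{-5}]$ cm²/s and $\beta$ in
$[0, 0.7]$. The start point is fixed ($\beta = 0.25$, BFI $= 10^{-8}$) with
three deterministic fallback starts, so fits are exactly reproducible.
Presets mirror the two study configurations: `arm-raw` (all 45 nonzero
delays of the 46-delay forearm curves) and `pfc-onboard` (first 12 nonzero
delays of the on-board grid, where later delays are noise-dominated). The
per-window residual is the RMS of model minus data over the fitted delays;
a trial is excluded when the median of these residuals exceeds 0.03
(strictly — boundary trials are kept, with a $10^{-12}$ tie guard against
floating-point representation).

Short correlator windows bias $g_2$ by a roughly additive offset (the
window mean in the denominator is estimated from the same data as the
numerator). `correct_g2_offset()` anchors the mean of the last quartile of
delays to 1 before fitting; it refuses (with a warning) when the tail has
visibly not decorrelated, since anchoring would then subtract genuine
correlation. This matters in practice: in the end-to-end simulations the
correction reduces the recovered-BFI bias severalfold, but it is only valid
when the delay grid extends well past the decorrelation time — which is why
the forearm configuration pairs slow flow with a 460 µs grid and the
cerebral configuration pairs fast flow with a 50 µs grid.

## Pulse markers and pulsatility

`estimate_pulse_rate()` takes the mean-subtracted trace, zero-pads it
fourfold, and reports the frequency of the largest non-DC magnitude peak;
a pulse is declared only when that peak falls in 0.33–2.65 Hz (twice the
resting adult heart-rate band). The native resolution 1/duration (0.067 Hz
for 15 s, 0.13 Hz for 7.5 s) matches the quantization of count-based rates:
8 beats in 7.5 s give 1.07 Hz, 7 beats 0.93 Hz.

`detect_markers()` finds systolic peaks as strict local maxima separated by
at least $0.6/\text{rate}$ seconds (the minimal-distance rule is a
frequency if read literally; the only physically coherent reading is as a
time, and that is what is implemented), diastolic ends as minima between
consecutive SPs, dicrotic notches as the earliest strict local minimum in
$( \mathrm{SP}, \mathrm{SP}+0.4\,\mathrm{s}]$ before the next DE, and
diastolic peaks as strict maxima between DN and DE. Ties break toward the
earlier sample; partial boundary cycles yield no markers; beats whose
DN/DP cannot be resolved as distinct strict extrema are dropped and
counted. The pulsatility index is
$(\langle\mathrm{BFI}\rangle_{SP} - \langle\mathrm{BFI}\rangle_{DE}) /
\langle\mathrm{BFI}\rangle$, scale-invariant by construction.

## Noise model

`g2_noise_at_markers()` treats all records at one pulse phase as repeated
measurements under similar flow: the per-delay noise is the sample SD
($n-1$ denominator, appropriate for the ~8–15 markers per trial) across
marker-selected records, averaged over nonzero delays (whether the average
spans all nonzero delays or the fitted subset is switchable; all-nonzero is
the default). Markers map to the nearest window start; collisions keep both
draws. With stationary flow the conditioning is vacuous and the metric
equals the unconditioned across-window SD, which is tested. Pixel subsets
in `noise_vs_pixels()` are drawn without replacement under a fixed seed,
making the scaling curves reproducible; on simulated independent-pixel
streams the fitted log-log slope is $-0.5$ and the single-pixel to
1024-pixel noise ratio is 32.

## Group statistics

`normalize_trial()` rescales each trial to 100% of the median of its first
control segment, cancelling the absolute-BFI uncertainties.
`lme_contrast()` fits rBFI ~ Trial + Condition + (Condition | Subject) via
lme4/lmerTest with Satterthwaite p-values, with Trial as a categorical
per-trial fixed effect (the open design choice; an index covariate would
impose an arbitrary ordering). Because those per-trial intercepts absorb
subject-level intercepts, a zero random-intercept variance is expected and
benign; the fallback to a random-intercept-only model therefore triggers
only when the condition-slope variance itself degenerates (or the fit
fails). Under the synthetic cohort generator's null the empirical type-I
error at $\alpha = 0.05$ is 0.08 over 200 replicates — slightly
anticonservative, driven by replicates where the slope variance collapses —
and the power for the study-regime +12% shift at 15 subjects exceeds 0.8.
P-values are reported raw (uncorrected), as in the underlying study design,
with 0.05/0.01/0.001 star conventions.

The synthetic cohort generator (`simulate_trial_table()`) draws per-trial
intercepts (SD 6 percentage points), per-subject condition slopes (SD 3)
and residuals (SD 5) around a 100% control level — chosen once as a
realistic regime in which the published effect sizes (+12% cerebral
activation, Cohen's d near 1) are comfortably but not trivially detectable.

## Problem sizes and numerical choices

Desk-scale simulation sizes were chosen once as a compromise between
estimator bias, Monte-Carlo error and runtime, and are stated here as the
package's own study conditions:

- SNR parallelization check: 1024 pixels, 220 windows of 200 frames at 3 µs
  (44,000 frames), 0.1 events/frame.
- End-to-end BFI recovery: 1024 pixels, 32 windows of 4,000 frames at
  3.37 µs (128,000 frames), SDS 4 cm, 0.05 events/frame. Windows of 4,000
  frames keep the finite-window estimator bias well below the 10% recovery
  criterion; the hardware's physical windows (tens of thousands of frames)
  are longer still.
- Closed-loop suppression: 256 pixels, 10 windows of 4,000 frames at 10 µs
  per segment, the forearm configuration.
- Mixed-model calibration: 200 null replicates, 60 power replicates.

Optimizer tolerances are `ftol = ptol = 1e-15` (effectively machine
precision, needed for the 1e-6 self-consistency property); the circulant
embedding pads to the next power of two of twice the segment length;
identical seeds give bit-identical streams, and all seeded draws restore
the caller's RNG state.

## Known limitations

- The semi-infinite homogeneous model is the only forward model;
  multi-layer models are deliberately out of scope (the underlying study
  found them unreliable at these delay counts).
- Absolute BFI accuracy is limited by assumed optical properties and by the
  binarization and finite-window effects discussed above; conclusions
  should rest on normalized BFI, as in the group analysis.
- The simulator's independence across pixels makes the $\sqrt{M}$ law exact
  by construction; real arrays lose some of this gain to pixel cross-talk,
  uneven photon detection efficiency and partially shared speckles.
- On-disk containers are plain text (CSV + JSON sidecar); at the full
  hardware scale (250,000 pixels at hundreds of kfps) a chunked binary
  store would be required instead.
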