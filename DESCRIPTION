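Package: pdcs
Title: Parallelized Diffuse Correlation Spectroscopy Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for parallelized diffuse
    correlation spectroscopy (PDCS) with single-photon avalanche diode (SPAD)
    arrays. Generates synthetic binary photon-count frame streams whose
    statistics follow the semi-infinite correlation-diffusion model of blood
    flow in tissue, estimates multi-pixel intensity autocorrelations g2(tau),
    fits the Siegert-chained semi-infinite model for a blood flow index (BFI)
    and coherence factor beta, detects pulse waveform markers (systolic peak,
    diastolic end, dicrotic notch, diastolic peak) and the pulsatility index,
    computes marker-conditioned g2 noise with its square-root-of-M
    multi-speckle scaling, and runs trial normalization, effect sizes and
    linear mixed-effects condition contrasts at the group level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    minpack.lm,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
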