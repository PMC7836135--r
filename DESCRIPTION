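Package: ssvepmod
Title: Steady-State Visual Evoked Potential Brain-Behavior Moderation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for steady-state visual evoked
    potential (SSVEP) studies of visual unpleasantness. Generates synthetic
    multi-channel EEG with a plantable 25 Hz SSVEP, pink noise and artifacts;
    preprocesses continuous recordings (mastoid re-reference, windowed-sinc
    high-pass, Fourier resampling, line-noise notch, overlapping epochs with
    amplitude-based rejection); applies a spherical-spline surface Laplacian
    (current source density) spatial filter; estimates Hamming-tapered power
    spectral density at the stimulation frequency; and fits two-stage
    multilevel moderation models relating cortical excitation and stimulus
    brightness to unpleasantness ratings, with model-comparison F tests,
    partial eta-squared effect sizes, electrode-wise Benjamini-Hochberg FDR
    correction, and bootstrapped correlation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
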