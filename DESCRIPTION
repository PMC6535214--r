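Package: rhythmsim
Title: Simulation and Detection Benchmarking of Large-Scale Rhythmic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates feature-by-sample abundance data (e.g., circadian
    transcriptomes) in which rhythmic and non-rhythmic features are measured
    at multiple time points in one or more conditions. Expected abundance
    follows a flexible rhythmic model with per-group amplitude, phase,
    period, waveform and baseline, where amplitude and baseline may be
    time-dependent (damped rhythms, drift). Measurements are sampled from
    Gaussian or negative binomial distributions, the latter with a
    mean-dispersion relationship approximating RNA-seq counts. Includes
    cosinor (harmonic) regression for rhythm detection, prediction
    intervals for both sampling families, and AUROC-based scoring of
    detection accuracy against the simulation ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
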