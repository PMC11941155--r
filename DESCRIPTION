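Package: pdeeg
Title: EEG Band-Power Pipelines for Parkinson's Disease Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for screening Parkinson's disease from resting-state scalp
    EEG. Implements the full analysis chain: reading EDF, BrainVision and
    plain-matrix recordings; zero-phase Butterworth band-pass filtering into
    the five canonical frequency bands (delta, theta, alpha, beta, gamma);
    ICA-based removal of eye-blink artifacts using the frontopolar channels
    Fp1/Fp2 as ocular proxies; segmentation into 1-s epochs; Welch
    power-spectral-density band-power features; a per-band linear support
    vector machine baseline and a compact band-stacked 2D convolutional
    network classifier; subject-dependent and subject-independent
    cross-validation with confusion-matrix, ROC and AUC reporting. A
    synthetic cohort generator with planted spectral group effects (elevated
    theta, depressed beta and gamma power in patients) makes every stage
    testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
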