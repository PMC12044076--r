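Package: sleepcrit
Title: Complexity and Criticality Analysis of Sleep EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying how a psychoactive intervention
    shifts sleep-EEG dynamics: Welch power spectra with aperiodic (1/f) model
    fitting and 1/f-corrected band power, sample entropy, spectral entropy and
    its sample-entropy variant, normalized Lempel-Ziv complexity, detrended
    fluctuation analysis, paired permutation pseudo-T inference with
    maximum-statistic family-wise error control, and cross-validated decoding
    (SVM, LDA, random forest with grouped nested cross-validation). Includes a
    synthetic sleep-EEG generator with controllable spectral slope and
    oscillatory peaks so every stage is verifiable against known ground truth,
    plus minimal European Data Format (EDF) input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    MASS,
    e1071,
    ranger,
    tibble,
    dplyr,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
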