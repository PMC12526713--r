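Package: weanEMG
Title: Weaning-Outcome Classification from Diaphragmatic Surface EMG and ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify mechanical-ventilation weaning outcome
    (success versus failure) from simultaneous 3-lead ECG and 5-channel
    diaphragmatic surface EMG recordings. Implements the full analysis
    chain: zero-phase filtering and resampling; derived cardiorespiratory
    signals (ECG-derived respiration, heart-rate variability, EMG envelope
    and interpolated EMG); time-varying Welch spectral band parameters,
    magnitude-squared coherence, and approximate/sample entropy; a
    320-feature summary catalogue with Mann-Whitney and Spearman feature
    selection; and Naive Bayes, k-nearest-neighbour and support-vector
    classifiers with sequential backward feature elimination evaluated
    over repeated stratified splits. A synthetic cohort generator
    emulating the statistical structure of such recordings is included so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
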