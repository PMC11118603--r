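Package: iednet
Title: Window-Level Detection of Epileptiform Discharges in ICU EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects interictal epileptiform discharges (spikes and sharp
    waves) in continuous intensive-care-unit electroencephalography at the
    resolution of 160 millisecond windows. Provides a seeded generator of
    annotated synthetic scalp EEG written as EDF(+), EDF(+) reading and
    writing with annotation support, derivation of the 16-channel
    longitudinal bipolar ("double banana") montage, zero-phase FIR
    resampling to 125 Hz, non-overlapping 20-timestep windowing with
    per-channel min-max normalization and onset-based binary labeling
    (including a k-windows-early lookahead scheme), stratified
    train/validation/test splitting with inverse-frequency class weights,
    gated-recurrent-unit and convolutional classifiers trained with
    class-weighted cross-entropy and best-epoch selection, and an
    evaluation suite reporting accuracy, sensitivity, specificity and
    balanced accuracy together with zero-rule baselines and an
    early-detection sweep.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
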