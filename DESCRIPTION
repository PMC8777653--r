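Package: apneaband
Title: Subband Contribution Analysis for Sleep Apnea Detection from
    Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects obstructive sleep apnea from single-lead
    electrocardiogram recordings sampled at 100 Hz. Decomposes each
    recording with equal-width fourth-order Butterworth bandpass filter
    banks (1, 2, 4 and 8 bands tiling 0.5-49.5 Hz, 15 subbands in all),
    z-score normalises one-minute segments, and classifies each minute as
    apnea or normal with a one-dimensional convolutional neural network
    trained by Adam on cross-entropy. Per-minute accuracy, sensitivity and
    specificity and per-recording apnea-hypopnea-index (AHI) diagnoses are
    reported in tidy tables. Ships the recording-to-subject map of the
    PhysioNet Apnea-ECG cohort with subject-dependent and
    subject-independent splits and a leakage audit, a WFDB and plain-text
    reader/writer, and a synthetic ECG generator with apnea-driven cyclic
    heart-rate variation so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
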