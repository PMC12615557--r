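Package: specdecode
Title: Spectral Parameterization and Multivariate Decoding of Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end resting-state EEG spectral analysis: synthetic cohort
    simulation with known 1/f-plus-peaks structure and planted brain-behavior
    associations, FIR filtering and artifact-criterion preprocessing to binned
    power spectra, decomposition of each spectrum into periodic (Gaussian peak)
    and aperiodic (offset, exponent) components, per-frequency-bin linear
    support-vector-regression decoding of behavioral scores with repeated
    cross-validation, permutation-based inference with frequency-bin cluster
    correction, and the accompanying rank-based correlation statistics with
    Holm and false-discovery-rate adjustment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
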