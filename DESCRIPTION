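Package: leadtime
Title: Single-Lead Time-Resolved Decoding and Latency Timeline Reconstruction
Version: 0.1.0
Authors@R: person("leadtime", "maintainers", email = "leadtime@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for response-locked intracranial (stereoEEG-style)
    trial data: Morlet wavelet power features, per-lead per-timepoint shrinkage
    LDA decoding of the left/right decision with balanced label-shuffle
    permutations, temporal cluster statistics with FDR control, single-trial
    onset latency detection on decision-value and power-contrast traces,
    pairwise area onset-difference matrices with leave-one-lead-out
    bootstrapping, iterative one-dimensional (MDS-style) timeline
    reconstruction, and a cross-method rank consensus with a clustering score.
    Includes a synthetic-data generator with planted, configurable spectral
    effects and known onset times for validation and parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
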