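Package: qparfp
Title: Quantitative Pattern-Activity Relationship Modelling of
    Chromatographic Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating whole HPLC fingerprints of complex herbal
    extracts to a measured bioactivity (quantitative pattern-activity
    relationship, QPAR). Provides a synthetic multi-batch fingerprint
    generator, baseline correction and alignment, similarity-index and PCA
    diagnostics, Kennard-Stone sample selection, NIPALS partial least
    squares with leave-one-out component selection, elastic-net variable
    selection with PLS refit on the selected support (EN-PLS), the standard
    validation metric suite (R2, RMSET, RMSECV, RMSEP, q2, per-sample
    REP/PRESS), and a region-perturbation sensitivity analysis that maps
    chromatogram regions to predicted bioactivity changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
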