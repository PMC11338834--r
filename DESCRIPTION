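Package: scdemon
Title: Single-Cell Decorrelated Module Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers gene co-expression modules from single-cell expression
    matrices. Gene-gene correlations are computed on sample-decorrelated (ZCA
    whitened) data through an analytic truncated-SVD approximation, calibrated
    against gene-pair sparsity by 2D binning, bivariate spline smoothing and
    z-scoring, stabilized by bootstrapping over experimental batches, and
    clustered into modules by multigraph Leiden community detection across a
    ladder of eigenvalue powers. Includes module scoring, covariate and
    differential-expression enrichment statistics, module-module correlation
    networks, embedding contour smoothing, and a negative-binomial synthetic
    data generator with planted modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    mgcv,
    mclust,
    data.table,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
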