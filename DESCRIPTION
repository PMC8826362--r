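Package: qolnet
Title: Regularized Partial-Correlation Networks for Quality-of-Life Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end estimation and comparison of regularized
    partial-correlation networks (Gaussian graphical models) over
    longitudinal quality-of-life questionnaire scales: copyMean
    longitudinal imputation, Spearman screening with Benjamini-Hochberg
    adjustment, mixed Pearson/polyserial/polychoric correlation matrices
    with positive-definiteness repair, graphical LASSO with extended-BIC
    penalty selection, weighted-network centrality and modularity-based
    community detection, case-dropping bootstrap stability
    (CS-coefficient), nonparametric bootstrap edge confidence intervals
    and difference tests, and a paired permutation test comparing
    networks across time points. Includes a synthetic two-timepoint
    cohort generator with known sparse latent network structure for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    mvtnorm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
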