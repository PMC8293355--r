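Package: bridgenet
Title: Multilayer Partial-Correlation Networks of Cognition and Brain Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and stability analysis of regularized partial-correlation
    (Gaussian graphical model) networks spanning cognitive task scores and brain
    structural covariance layers (cortical volume, fractional anisotropy).
    Provides EBIC-selected graphical lasso estimation with pairwise-deletion
    correlations, strength and bridge-strength centrality with a one-standard-
    deviation classification rule, Walktrap community detection with weighted
    modularity, case-drop bootstrap correlation-stability (CS) coefficients,
    edge-weight bootstrap intervals, and a calibrated synthetic multilayer data
    generator with nested layer sample sizes and per-variable missingness.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
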