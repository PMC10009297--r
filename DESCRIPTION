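Package: resilnet
Title: Multi-Group Psychometric Network Analysis of Ordinal Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and comparing Gaussian graphical models of
    ordinal survey scales across groups. Implements survey cleaning
    (straight-line response exclusion, age subsetting, internal consistency,
    topological-overlap screening of redundant item pairs), sparse partial
    correlation networks via recursive significance pruning with
    covariance-selection maximum likelihood fits and SEM-style fit indices,
    expected influence and normalized bridge expected influence centrality
    for two-community item sets, permutation-based network comparison tests
    (global and edge/node level), posterior-predictive structure tests based
    on symmetric Kullback-Leibler divergence, case-drop bootstrap stability,
    and cross-group variability networks. Includes a latent-Gaussian
    synthetic-data generator with planted network structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
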