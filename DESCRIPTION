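Package: bayeswgr
Title: Bayesian Whole-Genome Regression for Large-Effect QTL Detection
    and Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-site Gibbs samplers for the Bayesian alphabet of
    whole-genome regression models (BayesB, BayesC, BayesC0 and the
    marker-effect formulation of GBLUP) with fixed hatch-within-generation
    effects, 1-Mb window posterior-variance reports for QTL detection,
    pedigree-based BLUP with EM-REML variance components, and a
    forward-in-time validation harness measuring prediction accuracy,
    persistence across generations and shrinkage bias. Includes a
    multi-generation breeding-population simulator (pedigree meiosis with a
    Haldane map, polygenic background plus one configurable large-effect
    QTL) that provides ground truth for all comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    tools,
    stats,
    utils,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
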