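Package: semGRN
Title: Two-Stage Penalized Least Squares for Large Systems of Structural
    Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs large systems of structural equations, such as
    gene regulatory networks inferred from paired expression and genotype
    data, by two-stage penalized least squares (2SPLS): ridge regression
    with generalized cross-validation estimates the conditional expectation
    of each endogenous variable given all exogenous variables at the first
    stage, and an adaptive lasso with K-fold cross-validation selects and
    estimates regulatory effects at the second stage. Includes a simulator
    for genetical-genomics benchmark designs (acyclic and cyclic topologies,
    hub nodes, correlated cis markers, heavy-tailed errors), single-equation
    adaptive lasso (AL) and two-stage adaptive lasso (2SAL) baselines,
    paired-bootstrap edge confidence, a power/FDR evaluation harness, and
    TSV-based input/output with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
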