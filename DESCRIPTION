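Package: liabgen
Title: Bayesian Threshold-Model Genomic Analysis of Ordinal Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic analysis of ordinal (liability-scale) traits in
    livestock cohorts. Provides SNP-panel quality control and panel
    merging, VanRaden genomic relationship matrices with principal
    component coordinates, a Gibbs sampler for the Bayesian threshold
    (liability) animal model with heritability summaries, BayesB
    whole-genome regression with 1-Mb window posterior probabilities of
    association, candidate-gene single-SNP scans with MCMC
    pseudo-p-values, exact and Monte Carlo Fisher tests on r x c
    contingency tables, and a synthetic-data generator that emulates the
    cohort structure the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
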