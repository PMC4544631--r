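Package: crossgs
Title: Genomic Selection Across Inbred Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection studies in multi-family inbred
    breeding populations genotyped with dominant (presence/absence) markers.
    Simulates doubled-haploid and recombinant-inbred-line families on a
    genetic map, adjusts field phenotypes against control cultivars
    replicated in sub-blocks and estimates line-mean heritability, fits
    five genomic prediction models (ridge-regression BLUP, Bayesian ridge
    regression, Bayesian LASSO, GBLUP on a marker kinship, Gaussian-kernel
    RKHS regression and Random Forest), estimates marker-based kinship and
    linkage disequilibrium, and evaluates predictors under single-,
    composite- and cross-population cross-validation, including a
    simulation experiment that quantifies how cross-population prediction
    accuracy decays as the training and validation populations share fewer
    trait QTLs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    randomForest,
    lme4,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
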