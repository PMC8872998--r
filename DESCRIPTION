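Package: slopekit
Title: Treatment-Slope Estimation and Expression-Based Prediction for
    Early-Intervention Cohorts
Version: 0.1.0
Authors@R:
    person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for modelling longitudinal treatment outcomes in
    early-intervention cohorts and predicting subject-specific treatment
    slopes from pre-treatment clinical measures and blood leukocyte gene
    expression. Provides a synthetic-cohort simulator with configurable
    random-intercept/random-slope trajectory structure and an embedded
    sparse expression signal; random-slope linear mixed-model fitting with
    BLUP slope extraction and a permutation test for group differences in
    slope variability; microarray-style preprocessing (quantile
    normalization, variance filtering, train-fit/test-apply covariate
    residualization); nested leave-one-out LASSO prediction with inner
    cross-validated penalty selection and a full-pipeline permutation null
    for cross-validated MSE; gene-set odds-ratio enrichment with
    Benjamini-Hochberg FDR; a network edge-count permutation test; and a
    voxelwise one-sample t-test with FDR thresholding for spatial
    expression maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
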