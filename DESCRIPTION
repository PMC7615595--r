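Package: cmrpheno
Title: Data-Driven Cardiometabolic and Renal Phenotyping of Survey Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and monitoring cardiometabolic and renal
    phenotypes in repeated cross-sectional health-examination surveys.
    Implements multivariate data cleaning with a pairwise Mahalanobis
    outlier screen, derived risk-factor computation (BMI, waist-to-height
    ratio, non-HDL cholesterol, CKD-EPI eGFR), sex-stratified standardized
    k-means phenotype discovery with elbow and silhouette diagnostics,
    bootstrap Jaccard cluster-stability assessment with an uncorrelated
    Gaussian null calibration, and survey-weighted age-standardized
    prevalence trends and membership-predictor regressions. A synthetic
    cohort generator emulating the mixture structure of a national
    examination survey makes the whole pipeline testable without access
    to restricted or bulky survey files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster
Config/testthat/edition: 3
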