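Package: shockpipe
Title: EHR Pre-Processing and Cardiogenic Shock Prediction Pipeline
Version: 0.1.0
Authors@R:
    person("Shockpipe", "Developers", email = "maintainers@shockpipe.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for coded electronic-health-record
    data: ICD-9 cohort selection, variable clustering with first-recorded
    aggregation, unit standardisation and decimal-shift repair, four
    multivariate missing-data imputation engines (chained equations with
    gradient-boosted conditional models and predictive mean matching,
    k-nearest-neighbour imputation, SoftImpute and iterative low-rank SVD
    completion), a Kolmogorov-Smirnov / Benjamini-Yekutieli imputation
    quality framework, SMOTE plus Edited-Nearest-Neighbours class
    rebalancing, and repeated stratified cross-validation of a
    gradient-boosted tree classifier for cardiogenic shock.  A synthetic
    cohort generator emulates the statistical structure of an intensive-care
    acute-coronary-syndrome population so the whole pipeline is exercisable
    without access to credentialed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    FNN,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
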