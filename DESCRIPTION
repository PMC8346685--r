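Package: roiclass
Title: Multi-Site ROI Classification with Harmonization, Repeated
    Nested Cross-Validation and Permutation Significance
Version: 0.1.0
Authors@R:
    person("ROI", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for group classification studies on region-of-interest
    (ROI) brain imaging tables pooled across acquisition sites. Provides
    feature schemas for Desikan-Killiany cortical / FreeSurfer subcortical
    and JHU white-matter atlases, empirical-Bayes (ComBat) location/scale
    site harmonization, class-imbalance correction by random undersampling,
    min-max ROI scaling, a linear support vector classifier and a small
    fully connected network, a repeated stratified 80/20 + 10-fold
    grid-search evaluation protocol, permutation-based significance for
    classifier performance, a frequency distribution comparison index for
    model comparison, and ROI importance maps from SVC coefficients or
    network weight backtracking. Includes a multi-site synthetic cohort
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
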