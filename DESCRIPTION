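Package: habsuit
Title: Ensemble Habitat Suitability Modeling for Invasive Plant Risk Assessment
Version: 0.1.0
Authors@R: person("Maintainer", "Anonymous", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A seeded, config-driven presence-background species distribution
    modeling workflow aimed at invasive plant early detection and rapid
    response. Covers occurrence record cleaning, kernel-density and
    target-guild background generation, predictor harmonization and
    collinearity screening, five modeling algorithms (stepwise GLM, MARS,
    boosted regression trees, random forest, and a maxent-style penalized
    logistic regression) behind one interface with overfitting and quality
    gates, 10-fold cross-validated evaluation, four binarization thresholds,
    equal-weight binary-map ensembles, multivariate environmental similarity
    surfaces (MESS), permutation variable importance, and management-unit
    risk summaries. Ships a virtual-species fixture generator so the entire
    pipeline is testable end-to-end on synthetic landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
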