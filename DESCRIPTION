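Package: hsdm
Title: Hierarchical Species Distribution Modelling with Ensemble Weighting
    and Land-Use Change Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-scale (national / provincial) species distribution
    modelling of wintering waterbird habitat. Fits an ensemble of six
    presence-background learners (boosted trees, GAM, GLM, maxent-style
    penalized logistic, random forest, SVM) combined by TSS-weighted
    averaging, evaluates models with seven presence-background metrics
    including the continuous Boyce index, binarizes suitability at the
    maximum-sensitivity-plus-specificity threshold, simulates land-use
    change with a patch-generating cellular automaton driven by a learned
    transition-suitability surface, and overlays coarse climatic and fine
    local suitability into final habitat maps with refugia, change and
    protected-area gap accounting. Includes a synthetic-data generator with
    a known suitability truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    glmnet,
    ranger,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    MASS,
    jsonlite
Config/testthat/edition: 3
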