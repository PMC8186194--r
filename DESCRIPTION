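Package: ctrval
Title: Cardiothoracic Ratio Measurement, Workflow Simulation and
    Agreement Statistics
Version: 0.1.0
Authors@R:
    person("ctrval", "maintainers", email = "maintainers@ctrval.invalid",
           role = c("aut", "cre"))
Description: Tools to study how automatic (segmentation-based) and manual
    measurements of the cardiothoracic ratio (CTR) on frontal chest
    radiographs agree.  Provides a synthetic chest-phantom generator with
    ground-truth lung and heart masks and known CTR, a small trainable
    encoder-decoder (U-Net style) segmentation network, CTR extraction
    from masks via horizontal extreme points with clinical failure rules,
    simulators for manual-observer, AI-only and AI-assisted measurement
    workflows with excellent/good/poor outcome grading, and the agreement
    (Bland-Altman, coefficient of variation), correlation (R squared) and
    classification (sensitivity/specificity/AUC at standard, Youden and
    maximum-sensitivity cutoffs) statistics used in clinical validation
    studies of such measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
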