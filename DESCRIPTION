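Package: batchsim
Title: Simulation Benchmarking of Batch-Effect Correction with
    Quality-Control Replicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking batch-effect correction strategies in
    log2 gene expression data. Generates synthetic multi-batch cohorts with
    quality-control (QC) technical replicates, estimates calibration and
    deconvolution parameters (QC factors, batch means, batch-effect SD,
    per-gene residual SDs), injects known batch and treatment effects under
    balanced, unbalanced and reduced designs, fits per-gene ordinary least
    squares, fixed-effect, random-intercept mixed and empirical-Bayes
    location/scale adjusted models, and evaluates them by true/false
    positive counts under Benjamini-Hochberg control, ROC AUC and principal
    component diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    sva,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
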