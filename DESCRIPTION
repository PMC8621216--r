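Package: lusBline
Title: Frame- and Clip-Level Classification of A-Line and B-Line
    Artifacts in Lung Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for distinguishing normal (A-line) from abnormal
    (B-line) lung parenchyma in lung ultrasound clips. Provides a
    synthetic sector-scan phantom generator with controllable artifact
    content, severity and within-clip heterogeneity; beam masking and
    stochastic training-time augmentation; patient-grouped K-fold
    cross-validation with leakage-free routing of clips between
    frame-level training and clip-level inference pools; a compact
    truncated-VGG convolutional frame classifier with a single-precision
    Rcpp backend; a clip-level decision rule that calls a clip B-positive
    when at least one run of tau consecutive frames has B-line
    probability at or above a classification threshold t, together with
    a clip-averaging baseline and a full (t, tau) operating-point sweep;
    frame- and clip-level evaluation (ROC/AUC, confusion matrices,
    sensitivity/specificity) with per-fold aggregation; and Grad-CAM
    heatmaps for model explainability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    EBImage,
    pracma,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
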