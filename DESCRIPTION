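Package: sonolbp
Title: Multi-Site Ultrasound Texture and Elastography Classification of
    Non-Specific Low Back Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying non-specific low back pain
    severity from multi-site musculoskeletal ultrasound. Implements a
    57-feature-per-ROI texture and elasticity feature bank (first-order
    statistics, Haralick features from gray-level co-occurrence matrices,
    Galloway features from gray-level run-length matrices, local binary
    pattern histogram statistics, mean-frequency spectral features, and
    shear-wave-elastography summaries) over a 14-image acquisition protocol,
    ANOVA F-statistic percentile feature selection with per-fold
    standardization, nested cross-validated linear support-vector-machine
    classification with a full metric panel, feature-importance ranking and
    muscle/site/position attribution, and multi-site versus single-site
    feature-fusion comparison. Includes a synthetic cohort generator that
    emulates speckle-textured B-mode regions of interest and class-shifted
    elasticity so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
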