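Package: hemil
Title: Weakly Supervised Classification of H&E Tissue Microarray Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multiple-instance learning pipeline for hematoxylin-and-eosin
    stained tissue microarray (TMA) core images with patient-level weak
    labels. Provides Macenko-style stain normalization, tissue detection and
    region tiling, a pluggable region feature extractor (deterministic
    filter bank, optional CNN backend), a five-member cross-validated
    ensemble of isotonically calibrated linear support-vector machines for
    region-level class probabilities, quantile-function aggregation to a
    sigmoid-calibrated patient-level classifier with task-specific cut
    points, and concordance statistics (accuracy, sensitivity, specificity,
    Cohen's kappa with confidence intervals, odds ratios). A synthetic TMA
    cohort generator with the marginal structure of the CBCS3 breast-cancer
    study makes the full pipeline testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
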