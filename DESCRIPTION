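Package: enterovol
Title: Linear and Volumetric Quantification of Bowel Inflammation on
    MR Enterography-Like Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying terminal-ileal inflammation on 3D
    T2-weighted enterography-like volumes: seed-point centerlines and
    length of disease, manual and semi-automated (k-means partition +
    random-forest scoring) bowel-wall segmentation, distance-transform
    wall thickness, and segmentation volume.  Includes a synthetic bowel
    phantom generator with analytic ground truth, a longitudinal cohort
    simulator, and the longitudinal statistics used to judge biomarker
    responsiveness: mixed-effects change over time, percent change from
    baseline, intraclass-correlation agreement, and Pearson correlations
    with confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    randomForest,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
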