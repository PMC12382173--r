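Package: washmap
Title: Dual-Timepoint Contrast Wash-Out Mapping for Brain Tumor MRI
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds rapid wash-out / late-enhancement maps from two
    post-contrast T1-weighted 3D volumes acquired at an early (about 5 min)
    and a late (about 25 min) timepoint after contrast injection, and
    evaluates them for differentiating glioblastoma from brain metastases.
    Provides a synthetic contrast-kinetics phantom generator with ground
    truth, 6-degree-of-freedom multi-resolution rigid co-registration with
    robust intensity normalization, signed wash-out percentage maps with a
    three-class voxel labeling, semi-automatic lesion volumetry with
    wash-out, rCBV and ADC ratios, and the full statistical layer: Welch
    t-tests, tie-aware ROC analysis with Youden's J and DeLong confidence
    intervals, ICC(2,k) interrater reliability, linear probability models,
    and cohort simulation from published group summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
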