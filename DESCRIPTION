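Package: tibiaseg
Title: Attention U-Net Segmentation and Test-Retest Repeatability for Murine Tibia MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated segmentation of the mouse tibia in 3D gradient-echo
    MRI and for certifying the precision of the derived bone-volume biomarker.
    Provides MetaImage (MHD/RAW) volume input/output with voxel-spacing geometry,
    a synthetic tibia phantom cohort simulator with consecutive-day test-retest
    pairs and simulated annotators, a 2D attention-gated U-Net segmenter trained
    slice-wise with binary cross-entropy, volumetric overlap accuracy metrics
    (Jaccard index, volume intersection ratio, signed volume error, Hausdorff
    distance), and test-retest repeatability statistics (within-subject
    coefficient of variation with chi-square confidence intervals, Bland-Altman
    limits of agreement, Pearson agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'geometry.R'
    'metrics.R'
    'repeatability.R'
    'unet.R'
    'volume-io.R'
    'phantom.R'
    'cohort.R'
    'training.R'
    'cli.R'
    'tibiaseg-package.R'
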