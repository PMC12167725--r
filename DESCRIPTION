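Package: srfpet
Title: Automatic Split Renal Function Measurement in PSMA PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic measurement of split renal function (SRF) from
    dual-modality PET/CT volumes. Implements a trainable 3D U-Net kidney
    segmenter taking co-registered CT (Hounsfield units) and PET
    (standardized uptake value, SUV) channels, deep supervision with
    class-weighted categorical cross-entropy, largest-connected-component
    (26-connected) postprocessing, and the left renal function percentage
    (LRF%) statistic computed as the summed left-kidney SUV over the summed
    SUV of both kidneys. Includes a synthetic abdominal phantom simulator
    with analytically known ground truth, seeded paired augmentation of
    CT/PET/label patches, multi-reader agreement statistics (Dice-Sorensen
    coefficient, volume differences, Spearman correlation, Bland-Altman
    limits of agreement), and a command-line interface for simulation,
    training, segmentation, measurement, and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
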