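Package: patellometry
Title: Automated Patellofemoral Landmark Detection and Morphometry on Axial Knee CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated localization of seven patellofemoral
    landmarks on axial knee CT slices and derivation of four patellofemoral
    parameters (transepicondylar axis length, TEA-posterior femur axis angle,
    trochlear medial asymmetry ratio, sulcus angle). Implements the CT
    preprocessing chain (Hounsfield windowing, bone bounding-box detection,
    invertible 160x160 resampling, 36x36 patch extraction), a two-stage
    coarse-to-fine convolutional landmark regressor with multi-stage deep
    supervision and optional SimCLR contrastive pretraining, the geometric
    morphometry, and the evaluation statistics (Euclidean landmark error,
    precision at a distance threshold, paired and independent t-tests,
    Bland-Altman agreement). A synthetic knee-phantom generator with
    analytically known landmarks provides trainable, testable data at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    RNifti,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
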