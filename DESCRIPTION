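Package: petcam
Title: Weakly Supervised 3D PET Tumour Segmentation and Outcome
    Prediction with Prior-Constrained Class Activation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments tumours in 3D FDG-PET volumes using only image-level
    cancer-type labels and a single annotated point at the tumour centre.
    A convolutional classifier is trained on coronal and sagittal maximum
    intensity projections under a multitask objective that combines binary
    cross-entropy with a distance constraint on gradient-weighted class
    activation maps; the two 2D activation maps are thresholded and
    back-projected to reconstruct the 3D tumour mask, which feeds a small
    3D convolutional network for treatment-outcome prediction. Includes a
    synthetic PET phantom generator with physiological decoy uptake,
    overlap and classification metrics, and a stratified cross-validation
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
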