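Package: sctgan
Title: Synthetic CT Generation from CBCT with an SSIM-Weighted CycleGAN and
    Dosimetric Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic CT (sCT) images from cone-beam CT (CBCT) with a
    paired cycleGAN whose cycle loss is augmented by a thresholded, patch-based
    SSIM-weighted L1 term, so that regions where the CBCT disagrees with the
    deformably registered planning CT (gas pockets, anatomical change) are
    excluded from paired supervision and their CBCT structure is preserved.
    Ships a seeded digital pelvis phantom generator (CBCT cupping, noise and
    streak artifacts, deformed and mismatched registered CT, analytic pencil-beam
    dose), plus the full quantitative evaluation stack used for sCT commissioning:
    Dice, mean distance to agreement and Hausdorff contour metrics, CT-number
    fidelity with line profiles and Spearman correlation, HU to relative electron
    density conversion, cumulative DVH with Dx% statistics, and 3D global gamma
    analysis with a low-dose threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
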