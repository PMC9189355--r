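Package: cbctqi
Title: Improving Cone-Beam CT Image Quality by Deformable Registration and
    CycleGAN Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two routes for improving iterative cone-beam CT (CBCT) image
    quality in pelvic radiotherapy, implemented end to end on synthetic
    digital phantoms: (1) a three-stage coarse-to-fine 3D convolutional
    registration network trained unsupervised with a modality-independent
    neighborhood descriptor (MIND) loss plus a diffusion smoothness penalty,
    which deforms the planning CT onto the CBCT and propagates organ
    contours; and (2) a similarity-constrained CycleGAN that translates CBCT
    slices into synthetic CT. Includes the common preprocessing chain (skin
    mask, couch removal, air fill, resampling, rigid alignment, centered
    crop), the evaluation metrics (NMI, NCC, DSC, MAE, RMSE, PSNR, SSIM) and
    the organ volume-difference statistic, a seedable pelvic phantom
    generator with CBCT-style degradation and known ground-truth
    deformations, and a study driver that stratifies cases by bladder
    volume mismatch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
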