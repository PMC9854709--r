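Package: fdacnn
Title: Fully Dense Attention CNN for Undersampled MRI Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De-aliasing of sparsely sampled magnetic resonance images with a
    fully dense attention convolutional neural network (FDA-CNN). Provides a
    centered orthonormal 2D Fourier model of single-coil k-space, Cartesian
    under-sampling mask generators (2D Gaussian, 1D Gaussian, and a mixed
    center-periphery pattern), zero-filled reconstruction, dense-block
    encoder/decoder networks with attention gates plus a plain Unet baseline,
    mean-squared-error training with the Adam optimizer, and an image-quality
    harness (SSIM, PSNR, NRMSE, pixel-domain VIF). A seeded ellipse-phantom
    generator supplies paired ground-truth images and k-space so the whole
    pipeline is testable at desk scale without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
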