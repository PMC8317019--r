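Package: steerrec
Title: Roto-Translationally Equivariant Learned Reconstruction for Tomographic Inverse Problems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steerable convolutional building blocks for finite cyclic rotation
    groups, assembled into unrolled (learned) proximal gradient reconstruction
    methods for simulated low-dose computed tomography and subsampled Cartesian
    MRI. Provides the steerable kernel-constraint solver, equivariant
    convolution layers and nonlinearities, a ray-driven Radon transform with
    exact adjoint and filtered backprojection, masked-Fourier MRI operators,
    total-variation proximal operators, PSNR/SSIM image quality metrics with
    masked variants, seeded ellipse-phantom generators, and training utilities
    for width-matched comparisons of ordinary and equivariant networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
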