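Package: tfmuq
Title: Uncertainty-Aware Traction Force Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Traction force microscopy with uncertainty quantification
    (TFM-UQ). Estimates substrate deformation from fluorescent bead image
    pairs by FFT cross-correlation particle image velocimetry (PIV),
    quantifies the spatially varying measurement uncertainty of each
    displacement vector with a non-parametric pixel bootstrap validated by
    density-based clustering, and propagates that uncertainty through a
    hierarchical Bayesian inversion of the finite-thickness Fourier
    elastostatic problem using a hybrid Gibbs sampler. Produces pointwise
    traction stress magnitude and direction error maps, classical
    Tikhonov/L-curve baselines, and a fully synthetic bead-image benchmark
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
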