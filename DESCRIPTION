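Package: deeptmi
Title: Physics-Unrolled Reconstruction and Tumor-Margin Segmentation for
    Millimeter-Wave Skin Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and reconstructing millimeter-wave
    electromagnetic images of skin and segmenting them into tumor and
    normal regions. Implements the scattering forward model with its
    delay-and-sum (backpropagation) adjoint, the l1-regularized ISTA
    (forward-backward splitting) solver, and a recurrent auto-encoder
    obtained by unrolling ISTA into a physics-initialized network whose
    operator weights and per-layer shrinkage thresholds are trained
    without ground truth on the measurement-domain residual. A Cole-Cole
    dispersive tissue-phantom simulator generates labeled synthetic
    datasets, and segmentation figures of merit (IoU, SSIM, normalized
    MSE, rms relative error, tumor-to-clutter ratio) quantify recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
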