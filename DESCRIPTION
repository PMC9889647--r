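Package: leafseq
Title: Deep-Learning Leaf Sequencing for Adaptive Radiotherapy Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study deep-learning-based multi-leaf collimator (MLC)
    leaf sequencing for step-and-shoot IMRT replanning on an MR-Linac-like
    machine. Provides a synthetic cohort simulator (phantoms, step-and-shoot
    plans, an idealized attenuated back-projection dose engine), beam's-eye-view
    dose preprocessing, a conditional adversarial image-to-image network
    (U-Net generator, patch discriminator with spectral normalization)
    implemented with hand-derived backpropagation, conversion of predicted
    aperture channels to deliverable MLC control points and monitor-unit
    weights, and plan evaluation by gamma analysis and dose-volume histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
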