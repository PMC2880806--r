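Package: neurodyn
Title: Neurodynamical Simulation and Spatial ICA for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for stochastic neurodynamics and
    resting-state functional MRI. Implements stochastic-resonance models (a
    bistable double-well Langevin system and a two-variable Rinzel reduction
    of the Hodgkin-Huxley neuron driven by a periodic current plus noise),
    a discretized Wilson-Cowan linear network with stationary-covariance
    eigenmode analysis and Kuramoto synchrony, a seeded synthetic
    resting-state fMRI generator with ground truth, and a spatial FastICA
    pipeline (preprocessing, PCA whitening, fixed-point estimation,
    Z-scored thresholded maps, and ground-truth matching).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
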