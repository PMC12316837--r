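Package: hotspotmon
Title: Hotspot Detection for Microwave Breast Hyperthermia Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inversion toolkit for monitoring microwave breast
    hyperthermia with differential microwave tomography. Provides a synthetic
    2-D breast phantom with dispersive tissue dielectrics, a seeded random
    heating-scenario generator, a thermo-dielectric coupling model, a 2-D
    transverse-magnetic method-of-moments forward scattering solver with
    multi-static multi-frequency acquisition, an additive white Gaussian
    noise model, a convolutional encoder-decoder (implemented natively,
    trained with stochastic gradient descent) that maps differential
    scattered-field tensors directly to hotspot images, pixel- and
    scenario-level evaluation metrics, and a Born-iterative inversion
    baseline with Tikhonov, truncated-SVD, CGLS and FISTA regularizers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
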