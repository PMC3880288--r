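Package: oncovasc
Title: Hybrid 3D Tumor Growth, Angiogenesis and Chemotherapy Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid discrete-continuum simulator of three-dimensional solid
    tumor growth coupled to sprouting angiogenesis and cytotoxic chemotherapy.
    Tumor cells and endothelial segments live on a regular lattice; interstitial
    pressure is built from Gaussian-like cell- and vessel-induced kernels,
    interstitial fluid flow follows Darcy's law, and oxygen, carbon dioxide,
    tumor angiogenesis factor and drug are advanced by an explicit
    finite-difference diffusion-convection-reaction scheme. Cell fate is driven
    by an activity/vital-energy bookkeeping with pressure-directed division;
    vessel tips migrate up angiogenic-factor gradients, branch at sampled
    hotpoints, mature and are pruned. Includes growth-stage and morphology
    analytics, a dose-response harness, a parameter-sensitivity scan, and
    deterministic seeded runs with manifest-based reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
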