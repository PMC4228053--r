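Package: melovis
Title: Melanopsin-Contrasting Metamer Design and Visual Electrophysiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying melanopsin-driven light adaptation in mouse vision.
    Designs cone-metameric, melanopsin-contrasting light spectra ("daylight" vs
    "mel-low") by receptor silent substitution on a multi-primary LED model, using
    visual-pigment nomogram templates to compute alpha-opic effective photon fluxes.
    Simulates trial-structured dLGN single-unit recordings (linear-nonlinear-Poisson
    units with difference-of-Gaussians receptive fields) and flash electroretinogram
    (ERG) waveforms under both spectral conditions, and provides the analysis
    pipeline that quantifies condition-dependent changes in response gain,
    receptive fields, spatial and temporal frequency tuning, direction selectivity,
    trial-to-trial reliability, and pairwise signal correlation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
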