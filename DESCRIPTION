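Package: nvcoxy
Title: Neurovascular Coupling Metrics and Capillary Oxygen Transport Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neurovascular coupling and tissue oxygen
    supply in the brain microvasculature. Extracts red blood cell velocity,
    flux, haematocrit and vessel diameter from two-photon line-scan
    kymographs and XY movies; skeletonizes 3D vascular image stacks to
    measure capillary density, diameter-by-depth profiles and
    tissue-to-vessel distance distributions; detects calcium and metabolic
    (CMRO2) events, classifies vessel dilation responses against a shuffled
    null, and computes neurovascular coupling indices from imaging and
    combined laser-doppler/haemoglobin-spectroscopy recordings; and solves a
    Krogh-type radial oxygen diffusion model with Michaelis-Menten
    consumption, haemoglobin dissociation (Hill) and Henry's-law unit
    conversions, to estimate tissue oxygen profiles and the fraction of
    tissue in which low oxygen limits oxidative phosphorylation. Includes
    seeded synthetic-data generators for every input modality so the full
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
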