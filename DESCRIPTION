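Package: meascreen
Title: MEA-Based Analgesic Screening Analysis for iPSC-Derived Sensory Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for phenotypic analgesic
    screening on multiwell microelectrode arrays (MEAs) seeded with
    iPSC-derived sensory neuron-like cells. Provides extracellular spike
    detection (band-pass filtering, robust +/- k*SD threshold crossing with
    dead time), per-compound before/after screening statistics (normalised
    activity, paired Wilcoxon with FDR correction, robust z-prime, Cohen's d,
    active-channel counts) with composite hit calling and intensity tiering,
    LDH cytotoxicity and washout-reversibility filtering, Hill and Boltzmann
    concentration-response fitting with IC50 estimation, patch-clamp
    action-potential and I-V feature extraction with TTX-normalised
    inhibition, and a synthetic plate/sweep generator that emulates the
    statistical structure of the recordings so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
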