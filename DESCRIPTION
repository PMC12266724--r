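Package: sensint
Title: Multisensory Neural Circuit Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for claustrum-style multisensory circuit
    experiments: detection and classification of optogenetically evoked
    synaptic responses with a cortical-input integration statistic,
    delta-F-over-F event detection and uni-/multisensory taxonomy for axonal
    two-photon calcium imaging, signal-detection (d-prime) and
    reversal-learning metrics for three-port operant behavior, circadian
    relative amplitude and activity-bout statistics for home-cage actigraphy,
    and recording quality-control gates for intrinsic electrophysiology.
    Includes seeded synthetic-data generators for every input stream with
    ground-truth labels, so each stage is testable against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
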