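Package: gazeodd
Title: Gaze-Invariant Spatial Oddball Analysis of Cortical Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing spatial-oddball visual stimulation experiments
    recorded with chronic extracellular probes in freely behaving animals.
    Implements a balanced repeated-PCA response-intensity statistic (PC1/nPC1)
    on local field potential epochs, permutation-based significance tests
    within and across sessions, keypoint-based head/eye/viewing-angle
    estimation with first-view detection, and comparison of movement-evoked
    versus stimulus-evoked activity magnitudes. Ships a synthetic-session
    generator that emulates oddball schedules, position-specific adaptation,
    deviance gain, oscillatory evoked potentials, head-angle random walks and
    pupil-outline keypoints, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
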