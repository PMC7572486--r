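Package: tdrforage
Title: Dive Segmentation and Foraging Indices from Time-Depth Recorder Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for archival time-depth recorder (TDR)
    deployments on central-place foraging pinnipeds: zero-offset correction
    of sensor drift, dive detection at a 5 m threshold, descent/bottom/ascent
    phase segmentation, haul-out and foraging-trip segmentation, per-trip
    benthic/pelagic dive classification by splitting the bottom-time-weighted
    maximum-depth index at its density nadir, and per-trip foraging effort,
    success and efficiency indices (benthic dive rate, prey-capture
    probability, FTSI, FTEI, PBD). Includes a seeded synthetic deployment
    generator with ground truth for validation, and a builder for seasonal,
    lagged, standardised environmental covariate tables ready for
    mixed-model analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
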