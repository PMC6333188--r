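Package: vsmlc
Title: Analytic Virtual-Source Photon Fluence Model for a Rotated-Leaf
    MLC Linac
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-source analytic virtual-source model of a 6 MV linear
    accelerator equipped with an Agility-style multi-leaf collimator
    whose leaf bank is rotated ("defocused") to reduce interleaf
    leakage.  The model ray-traces a primary (target) and a secondary
    (head-scatter) virtual photon source through the rotated leaf bank
    with exponential attenuation in the tungsten-alloy leaves and
    predicts the in-line photon fluence at the isocenter plane for
    small fields.  Includes a synthetic phase-space generator for
    source extraction, profile-comparison metrics (distance-to-
    agreement at half maximum, 1D global gamma analysis, percent
    differences, absolute-dose conversion) and a scenario/sweep driver
    for parameter sensitivity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
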