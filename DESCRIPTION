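Package: fluorideKi
Title: Static 18F-Fluoride PET Quantification of Bone Metabolic Flux
Version: 0.1.0
Authors@R: person("PET", "Quantification Group", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies bone metabolic flux (Ki, plasma clearance to bone
    mineral) from a single static 18F-fluoride PET scan using a
    semi-population arterial input function reconstructed from two late
    venous plasma samples, via Patlak graphical analysis.  Includes the
    forward two-tissue (Hawkins) compartment model as a simulator and
    dynamic-Patlak oracle, standardized uptake value (SUV) computation,
    threshold-based lesion segmentation, well-counter calibration and
    decay correction, a progressive/non-progressive treatment-response
    classifier built on percentage change, and a synthetic cohort and
    phantom generator so that every stage of the pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
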