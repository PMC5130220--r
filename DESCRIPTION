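Package: bleedcap
Title: Colorimetric Bleeding-Detection Capsule Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for an ingestible
    bleeding-detection capsule that recognises intestinal bleeding from the
    colour of a hemoglobin-adsorbing film. Converts colour-sensor channel
    frequencies to RGB components via white-balance calibration and on to
    hue/saturation/lightness (HSL) features, applies a calibrated H/S decision
    region with severity grading, simulates the capsule's duty-cycled state
    machine with alarm telemetry and a power budget model, and generates
    synthetic dilution-series sensor streams so the whole pipeline can be
    exercised without hardware. Includes per-pixel raster classification and a
    small command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
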