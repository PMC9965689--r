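Package: bvic
Title: Branch Volumetric Ice Content Sensing Toolkit
Version: 0.1.0
Authors@R:
    person("BVIC", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Forward physics model, calibration, and freeze-thaw processing
    pipeline for impedance-reflection probes that monitor volumetric ice
    content in woody plant branches under cold stress. Models the branch as a
    gas/liquid/solid dielectric mixture in an equivalent RC circuit, converts
    probe impedance to a reflected-voltage signal on a coaxial line, fits and
    applies linear voltage-to-water-content calibrations, detects freezing
    from ambient temperature, and computes volumetric ice content and ice
    freeze-thaw rate time series with summary statistics. Includes a seeded
    synthetic-experiment simulator (chamber ramp and diurnal field protocols)
    with known ground truth for end-to-end validation, sensor
    characterization arithmetic (sensitivity, resolution, accuracy,
    environmental error, electrode coverage area), and a command-line
    interface for the simulate / calibrate / process / characterize
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
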