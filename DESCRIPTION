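Package: ivmflow
Title: Quantification of Tumor Growth and Microcirculation from Intravital
    Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying orthotopic tumor xenograft growth and
    functional microcirculation from two-channel intravital fluorescence
    microscopy of transparent chamber preparations (femur window and dorsal
    skinfold chamber). Provides tumor-area segmentation and relative growth
    curves with take-rate and censoring bookkeeping, vessel segmentation with
    skeleton-based centerline extraction, full-width-half-maximum diameter
    estimation, kymograph cross-correlation velocimetry, functional vessel
    density, blood flow rate (Baker-Wayland corrected) and tissue perfusion
    rate, effective vascular permeability estimation from intermittent
    FITC-albumin extravasation traces, repeated-measures ANOVA with
    Greenhouse-Geisser correction and Bonferroni post-tests, and a seeded
    synthetic-data generator that emulates the full experiment for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
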