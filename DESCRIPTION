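Package: glycoscape
Title: Nanoscale Glycocalyx Imaging and Metabolic Labeling Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipelines for nanoscale glycocalyx biology:
    scanning-angle interference microscopy (SAIM) height reconstruction via a
    transfer-matrix model of the silicon/oxide/buffer interference system and
    separable pixelwise nonlinear least squares; phasor-FLIM analysis of
    NAD(P)H decays with instrument calibration, compartment segmentation and
    bound-fraction maps; and stable-isotope (13C) isotopologue arithmetic for
    relative metabolite amounts and fractional contribution. Includes seeded
    synthetic-data generators for every stage so each inverse computation can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    readr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
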