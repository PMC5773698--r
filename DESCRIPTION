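Package: paglucose
Title: Image-Guided Photoacoustic Spectroscopy for Non-Invasive Glucose
    Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and chemometric analysis for scanning
    mid-infrared photoacoustic glucose monitoring on fingertip skin.
    Generates synthetic skin maps with friction ridges and eccrine sweat
    pores, models the raster-scanning photoacoustic instrument (Gaussian
    beam, wavenumber scans, lock-in averaging, pulse-energy normalization,
    cell resonance), selects secreting and non-secreting probe sites from
    the images, calibrates glucose against reference meter readings with
    from-scratch NIPALS partial least squares and principal component
    regression under leave-one-out cross-validation, and evaluates
    clinical accuracy with MARD, MAD and the Clarke error grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
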