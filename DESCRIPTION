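Package: epidpsm
Title: Pixel-Sensitivity-Map Determination for Portal Imager Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines the pixel-sensitivity map (PSM) of a radiotherapy
    electronic portal imaging device (EPID) by separating the
    detector-introduced non-uniformity from the beam-introduced
    non-uniformity in raw (non-flood-field-corrected) portal images.
    Implements four estimation methods (shifted small-field sampling with a
    2D not-a-knot spline beam-response fit, small-shift recursive
    pixel-ratio propagation, a three-stage shift/two-SID/quadrant pipeline,
    and concentric-ring radial averaging of an idealized symmetric image)
    together with a synthetic EPID and beam simulator providing ground
    truth, percentage-deviation and repeatability metrics, and a run-all
    comparison driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
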