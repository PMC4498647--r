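Package: coorient
Title: Co-Orientation Analysis for Two-Color Localization Microscopy
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies co-orientation - the simultaneous co-localization and
    orientational alignment of filamentous structures - in two-color
    single-molecule localization microscopy data. Localization tables are
    binned to histogram images and transformed into orientation-space
    representations with scale-selective, orientation-selective Fourier
    filters. A generalized cross-correlation between the two channels as a
    function of spatial lag and orientation difference yields co-orientation
    plots, summarized by an anisotropic Ripley's K statistic whose statistical
    significance is assessed with a rotation-based null model. Local
    co-orientation strength can be mapped across an image and rendered as an
    overlay. A wormlike-chain simulator generates two-channel synthetic
    localization data with known co-orientation structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    utils,
    data.table,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
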