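Package: organoscreen
Title: Morphometric Analysis of 3D Organoid Invasion Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for phenotypic high-content screening of 3D
    organotypic cultures. Segments two-channel (live/dead) maximum-intensity
    projections into organoid objects; computes per-organoid morphometrics:
    log-area, a shape-complexity statistic defined as the positive residual of
    a robust log(perimeter) on log(area) regression with its intercept lowered
    to the circle bound, and the dead-cell relative area; anchors per-well
    medians to plate controls (vehicle = 0, positive control = -100/+100);
    hierarchically clusters compound-by-concentration profiles and classifies
    compounds as growth-inhibitory, anti-invasive (strong/weak) or inactive.
    Includes a synthetic organoid image generator with known ground truth
    (round acini to stellate invasive shapes, Hill dose-response effects) so
    the whole pipeline is testable without microscopy data, and relative
    wound density metrics for 2D scratch-assay validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    pheatmap,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
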