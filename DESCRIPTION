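Package: colonykym
Title: Spatiotemporal Cell-Death and Sectoring Analysis for Bacterial Colony Time-Lapse Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatiotemporal cell death and clonal sectoring in two-channel
    (live reporter, dead stain) time-lapse movies of growing bacterial colonies.
    Provides time-projection preprocessing (rolling-ball background subtraction, rigid
    and translation registration, maximum-intensity projections, ratio images), radial
    space-time kymographs built by iterative centroid tracking and circumferential
    averaging, trainable random-forest pixel classification of colony sectors with
    Renyi-entropy automatic thresholding, and phase-resolved death statistics
    (phase windows, integrated death, phase ratios, wave-front speeds, Welch t
    strain comparisons). Includes a seeded synthetic colony-movie generator with
    per-strain presets and full ground truth, so the entire pipeline is testable
    end to end without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    tiff,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
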