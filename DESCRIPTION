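Package: holoscope
Title: Lensless In-Line Holographic Microscopy: Simulation, Phase
    Recovery, Quality Metrics and Cell Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a lensless on-chip in-line holographic
    microscope. Provides angular-spectrum free-space propagation of complex
    optical fields, a forward hologram simulator with ground-truth phantoms
    (USAF-1951 bar targets, disc phantoms mimicking cells and polystyrene
    microparticles), backpropagation reconstruction with iterative
    support-constrained phase recovery for twin-image suppression,
    full-reference image quality metrics (oblique-edge blur coefficient and
    a covariance-based quality index), USAF-1951 resolution scoring, and a
    deterministic watershed-based cell/particle segmentation and counting
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
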