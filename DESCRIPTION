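Package: pearbrowning
Title: Stochastic Image Analysis of Enzymatic Browning in Fresh-Cut Pears
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies enzymatic browning of fresh-cut pear slices from
    digital photographs on a magenta chroma-key background. Converts 8-bit
    sRGB rasters to CIE Lab* under a configurable illuminant/observer,
    segments slices by Lab*-interval thresholding, computes per-pixel
    Browning Index and Yellowing Index maps, extracts the shape factor of a
    three-parameter Weibull distribution fitted to each slice's index
    sample, classifies control versus antioxidant-treated slices with a
    kernel-density Bayes classifier under jackknife cross-validation, and
    compares the temporal trend of shape factors between groups with a
    common-slope regression plus residual diagnostics. A seeded synthetic
    image generator reproduces the statistical structure of the study design
    so the full pipeline is testable without the original photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lmtest,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
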