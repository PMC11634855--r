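Package: smearcount
Title: Red Blood Cell Counting in Smartphone-Microscope Blood-Smear Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for counting erythrocytes in brightfield photographs taken
    through low-cost clip-on smartphone microscopes.  Implements the full
    image chain for such captures: field-of-view isolation, square cropping,
    in-mask min-max normalization, tracked downscaling with exact
    micrometre-to-pixel bookkeeping, and a five-stage enhancement
    (Gaussian smoothing, edge sharpening, median filtering, contrast-limited
    adaptive histogram equalization, brightness/contrast adjustment).
    Detection uses a physical-unit Hough circle transform (gradient voting,
    with an exhaustive accumulator as reference), followed by minimum-distance
    suppression.  A validation layer computes detection precision/recall,
    count MAE/MSE and the linear fit between automatic and manual counts, and
    a seeded synthetic blood-smear generator provides images with exact
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    png,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    jpeg,
    tiff
Config/testthat/edition: 3
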