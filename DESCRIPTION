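Package: rootquant
Title: Root Image Analysis and Morphological Trait Extraction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measures morphological traits of washed plant roots from
    high-contrast scans. Segments dark roots on a bright background by
    global thresholding with component-size noise filtering, hole filling
    and optional contour smoothing; builds a one-pixel-wide,
    radius-annotated medial axis by ridge detection on an exact Euclidean
    distance transform, steepest-ascent connection and Guo-Hall thinning;
    classifies the skeleton into tips, branch points and segments with
    iterative radius-based pruning of invalid laterals; and reports the
    full trait set (length, diameters, areas, per-pixel cylinder surface
    area and volume, diameter-binned histograms, and whole-root-crown
    extent, convex hull, hole and angle traits) per image or region of
    interest, in batch, with ground-truth validation metrics (MBE, RMSE,
    R squared) and a synthetic wire-scene generator with analytic truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    png,
    tiff,
    jpeg
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
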