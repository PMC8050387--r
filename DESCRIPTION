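Package: neuritor
Title: Neurite Outgrowth Quantification from Two-Channel Live-Cell Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-content quantification of neurite outgrowth from two-channel
    live-cell microscopy fields (a Hoechst nuclei channel and a cell/neurite
    channel). Segments and counts nuclei by watershed splitting of a
    thresholded, illumination-corrected nuclei channel; detects thin
    curvilinear neurites with a multi-scale Hessian ridge (tubeness) filter,
    reduces them to unit-width skeletons outside cell bodies, and measures
    their physical length with 8-connected step weights. Per-field
    morphometrics (nuclei count, total and per-cell neurite length,
    neurite-positive cell fraction) feed condition-level comparisons: medians
    with percentile-bootstrap confidence intervals, one-sample and two-sample
    t tests, and one-way ANOVA with control comparisons. A built-in synthetic
    field generator with analytic arc-length ground truth makes every stage
    testable without real image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    png,
    igraph,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
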