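Package: netmanifold
Title: Low-Dimensional Manifold Embedding of Dynamic Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Embeds per-subject series of sliding-window functional
    connectivity networks onto a two-dimensional manifold and analyses the
    result. Region-of-interest time series are turned into sliding-window
    Pearson correlation networks, vectorized and stacked across subjects,
    reduced with principal components analysis, and embedded in 2D either
    linearly (top-2 component weights) or with t-SNE. Downstream tools
    classify conditions or groups with a radial-basis-function support
    vector machine under subject-grouped subsampling with majority voting,
    quantify spatial clustering of embedded series with within/between
    distance ratios and permutation tests, and map any embedded point back
    to its full correlation network for thresholded display and weighted
    graph summaries (global efficiency, local efficiency, assortativity).
    Includes a synthetic multi-subject cohort generator with block
    covariance structure, controllable condition/group effects, AR(1)
    temporal autocorrelation and volume censoring, so the whole pipeline is
    testable without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    igraph,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
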