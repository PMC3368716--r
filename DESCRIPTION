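Package: layercourse
Title: Multi-Layer Time-Course Network Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of multi-layer, time-resolved biological networks in
    which the same set of entities (genes, proteins, phenotypes) is
    replicated across layers of distinct biological measurements, each
    entity carrying one time-series vector per layer. Provides per-layer
    colour encoding of time-course values, per-time-point clustering of
    entities by distance geometry (classical multidimensional scaling
    truncated to three dimensions), detection of significant and recurrent
    cross-layer correlations with exact small-sample critical values,
    highlighting of the largest changes between consecutive time points,
    and two similarity-scoring schemes (vector average and the lower bound
    of the Wilson score confidence interval) with 0-10 binning. Includes a
    documented TSV/JSON input dialect, Pajek and edge-list export, a
    seeded synthetic-data generator with planted structures for
    validation, static snapshot rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
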