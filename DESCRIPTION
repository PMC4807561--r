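Package: compactr
Title: Comparative Pattern Counts for Time-Series Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discretizes per-gene time-series differential expression into
    regulation levels (up / no-change / down by default), encodes each gene's
    trajectory as a pattern vector per condition, and exhaustively
    cross-tabulates pattern pairs between two conditions into a two-way
    comparative pattern-count (COMPACT) matrix. Supports section partitioning,
    masking, layered exploration of common/novel/missing/altered gene sets,
    fold-change threshold sweeps, two-proportion z-tests on pattern counts,
    chord-diagram layouts with a Circos Table-Viewer-compatible export, and a
    synthetic planted-pattern expression simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
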