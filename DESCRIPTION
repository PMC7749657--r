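Package: ic50screen
Title: Dose-Response IC50 Profiling and Expression Correlation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plate-based viability normalization and Hill-equation IC50
    estimation across cell-line panels, genome-wide exact rank-correlation
    screening of expression patterns against IC50 profiles, hypergeometric
    gene-set overlap testing, and single-cell migration statistics (speed and
    time-penalized directional persistence). Includes seeded generators for
    synthetic plate-reader tables, planted-signal expression matrices with
    detection calls, gene sets, and persistent-random-walk cell tracks, so the
    full pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
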