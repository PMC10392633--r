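Package: exoquant
Title: Quantal Analysis of Amperometric Exocytosis Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell amperometry (SCA) and
    intracellular vesicle impact electrochemical cytometry (IVIEC)
    current traces: binomial smoothing, noise-floor estimation, threshold
    spike detection, per-event quantification (charge integration,
    molecule counts via Faraday's law, peak kinetics), per-cell
    aggregation, fraction-of-release computation with bootstrap
    confidence intervals, Mann-Whitney rank-sum group comparison, and
    Fura-2 ratiometric calcium trace averaging. Includes a synthetic-data
    generator with a ground-truth event ledger so the full pipeline can
    be exercised and validated without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
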