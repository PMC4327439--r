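Package: searchsccs
Title: Discovering Precursors of Health Events in Search Query Logs with
    the Self-Controlled Case Series Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for mining anonymized web search query
    logs for behavioral precursors of health events. Users likely to have
    experienced a condition are identified from self-identifying queries
    ("I was diagnosed with ..."), expanded into a larger cohort with a
    linear classifier tuned against published incidence rates, and their
    queries are generalized into categories through click-based
    encyclopedia page mappings. Per-category relative hazards of the event
    in a post-exposure risk window are then estimated with the
    self-controlled case series (SCCS) model via profile likelihood, with
    temporal-confound filtering and Benjamini-Hochberg false discovery
    rate control. A synthetic query-log simulator with planted ground
    truth (condition onsets, self-identification phrases, precursor
    exposures with known relative hazard, news-driven query spikes) makes
    every stage testable without access to proprietary search logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
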