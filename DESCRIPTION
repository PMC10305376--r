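Package: refcover
Title: Database Coverage Diagnostics for Systematic Review Literature Searches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how well bibliographic databases cover a body
    of eligible studies (for example, the randomized clinical trials on a
    clinical topic). Reads per-database record exports (RIS, MEDLINE flat
    text, CSV), clusters duplicate records across databases, attaches
    eligibility screening decisions, and computes retrieval diagnostics per
    database and per database combination: coverage/sensitivity, specificity,
    accuracy, and exact (Clopper-Pearson) binomial confidence intervals. A
    combination search finds minimal database sets reaching a target
    sensitivity, and a synthetic-corpus generator with planted ground truth
    (indexing structure, duplicate copies, eligibility labels) makes every
    pipeline stage testable without live database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    yaml
Config/testthat/edition: 3
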