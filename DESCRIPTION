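Package: pdactrials
Title: Census and Impact Scoring of the Pancreatic Cancer Clinical Trial Landscape
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to curate registry snapshots of pancreatic ductal
    adenocarcinoma (PDAC) interventional trials, expand multi-arm trials
    into per-intervention records, and tabulate landscape census tables
    under trial, intervention and systemic denominators with half-up or
    largest-remainder percentage rendering.  Phase III trials are ranked
    with an eight-criterion additive Impact Score rubric (novelty, prior
    promise, allocation design, progression-free and overall survival
    deltas, susceptible tumor fraction, desired impact, trial status).
    Includes controlled taxonomies for therapeutic categories and
    mechanisms of action, readers and writers for a JSON and a flat CSV
    registry dialect, and a seeded synthetic registry generator with
    exact categorical quotas so the whole pipeline is testable at full
    scale without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
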