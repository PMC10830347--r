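Package: adequacy
Title: Species-Level Data-Adequacy Metrics for Citizen-Science Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how adequate checklist-based citizen-science occurrence
    datasets are for monitoring individual species. Grids occurrence records and
    range maps onto a regular geographic grid, applies standard checklist
    filtering (complete lists only, shared-list deduplication, removal of
    exotic/vagrant/extinct/marine species and out-of-range records), and
    computes three per-species metrics: mean inventory completeness (MIC),
    total range completeness (TRC) and checklist spatial bias (CSB = 1 - H).
    Includes cumulative and annual temporal series with cross-species
    percentile summaries, trait-based linear models of adequacy, a synthetic
    world generator with known ground truth for end-to-end testing, and a
    config-driven pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
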