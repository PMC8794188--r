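Package: mcoselect
Title: Deterministic Gene Selection by Multiple Criteria Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects genes with the largest expression changes between case
    and control groups by computing Pareto-efficient frontiers over several
    conflicting performance measures, with no significance thresholds, no
    distributional assumptions and no user-tuned parameters. Supports
    individual analysis of one expression dataset with two or three location
    statistics (mean, median, mode, quantiles), meta-analysis of two to five
    datasets with one performance measure per dataset, successive frontier
    peeling into a ranked hierarchy, and a four-comparison sex-stratified
    scheme that isolates condition-specific genes by set algebra. Includes a
    synthetic-data generator with planted condition-responsive and
    sex-dimorphic genes, frontier visualisations, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lattice,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
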