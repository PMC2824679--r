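Package: palscreen
Title: Patient Active Learning for Semi-Automated Citation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automates Level-1 citation screening for systematic reviews
    with a multi-view ensemble of linear maximum-margin classifiers trained by
    pool-based active learning. Implements the Patient Active Learning (PAL)
    query strategy (random exploration until the diversity of labelled
    relevant citations converges, then SIMPLE uncertainty sampling over a
    randomly chosen feature-space), aggressive undersampling of the majority
    class before final training, sensitivity-first ensemble aggregation, and
    the Yield/Burden evaluation protocol for simulated screening experiments.
    Includes readers for CSV/TSV, RIS and MEDLINE citation files and a
    synthetic corpus generator with controllable prevalence and minority-class
    cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    kernlab,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
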