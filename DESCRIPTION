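Package: impulscreen
Title: Single-Cell GPCR Target Screening and 5-Choice Serial Reaction
    Time Task Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritising G-protein-coupled receptor (GPCR) drug
    targets by selective expression in cortical cell populations, and for
    scoring operant impulsivity experiments. Implements a single-cell
    differential-expression screen over gene-by-cell CPM matrices
    (per-set mean expression, log2 fold-change, signed detection-fraction
    separation, Wilcoxon rank-sum testing with Bonferroni correction, and
    G-protein-coupling filters), an explicit state-machine model of the
    5-choice serial reaction time task (schedule generation, agent-based
    session simulation, event-log classification, session metrics), the
    within-subject challenge statistics used to quantify drug effects
    (integer flooring of sparse percentages, log10 drug/vehicle ratios,
    one-sample and paired t-tests, Sidak adjustment, Pearson confound
    screening), and seeded synthetic-data generators with machine-readable
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
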