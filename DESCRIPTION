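Package: priorlasso
Title: Hierarchical Block-Wise Lasso with Prioritized Covariate Blocks
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds sparse, transportable prediction models from covariates
    organised in blocks (e.g. clinical variables, mutation indicators, gene
    expression) with a user-chosen priority order. Lasso models are fitted
    block by block in order of priority, the linear score of each step
    entering the next step as an offset with coefficient fixed to 1, so that
    predictive information shared across blocks is attributed to the block of
    highest priority. Supports continuous, binary and right-censored survival
    outcomes, optional cross-validated offsets, per-block caps on the number
    of selected variables, an unpenalized top block, and selection among
    candidate priority orders by cross-validated error. Includes an external
    validation suite for survival models (Uno's C-index, IPCW (integrated)
    Brier scores, maximal-logrank risk stratification, risk-group hazard
    ratios, calibration slopes and optimism) and a seeded synthetic
    multi-omics data generator with configurable cross-block redundancy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    survival,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
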