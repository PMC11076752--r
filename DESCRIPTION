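Package: boostfill
Title: Missing-Value Imputation for Mixed-Type Tables via Matrix
    Factorization and Gradient-Boosted Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes missing cells in mixed-type tabular data (continuous,
    categorical and Boolean columns) by combining rule-based preprocessing,
    adaptive low-rank matrix-factorization completion (non-negative matrix
    factorization for non-negative data, truncated singular value
    decomposition otherwise), and per-column gradient-boosted ensembles
    refined over sequential iterations. Includes a synthetic mixed-type data
    generator, a missing-completely-at-random masking harness and masked-cell
    evaluation metrics for benchmarking imputation accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
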