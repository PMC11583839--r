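Package: metabnet
Title: Mining Pipeline for Untargeted Plant Metabolomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable pipeline for LC-MS metabolomics feature tables:
    QC-aware noise filtering and missing-value triage, K-nearest-neighbour
    imputation, support-vector-regression drift normalization and batch
    integration anchored on pooled QC injections, spectral-library annotation
    with Metabolomics Standards Initiative confidence levels, differential
    accumulation statistics (Welch/Wilcoxon tests, false discovery rate,
    PLS-DA variable importance), hypergeometric enrichment over chemical
    taxonomy, pseudotargeted MRM ion-pair selection with cross-run feature
    matching, and iterative weighted-correlation-network module detection
    with eigenmetabolite and kME-based hub screening. Includes a synthetic
    data generator emulating multi-batch drift, intensity-dependent missing
    values and planted co-accumulation modules so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    mixOmics,
    optparse,
    yaml
Config/testthat/edition: 3
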