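Package: ageclock
Title: Construction, Evaluation and Application of DNA Methylation Age Clocks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for penalized-regression epigenetic clocks on DNA
    methylation beta values across mammalian species. Builds elastic-net
    clocks on transformed chronological age, applies pre-built clocks from
    coefficient tables with inverse age transformations, evaluates accuracy
    by leave-one-out and leave-one-species-out cross-validation, pre-filters
    CpG probes (mappability, middle-methylation, detection p-value), detects
    outlier arrays by inter-array correlation clustering, and performs
    epigenome-wide association studies of age with Stouffer meta-analysis
    across strata. Includes a seeded simulator of multi-species methylation
    cohorts so every analysis runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
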