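Package: liquidctc
Title: Rare-Cell Enumeration, Patient Stratification and Single-Cell
    Copy-Number Clonality for Liquid Biopsy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of slide-based liquid-biopsy assays for
    circulating rare cells. Classifies immunofluorescence cell events into
    the eight channel-based marker groups of the Landscape and EpCAM
    assays, enumerates cells per mL and per million nucleated cells, and
    compares cohorts with exact Mann-Whitney U tests. Stratifies patients
    from normal donors with a morphological hierarchy, out-of-bag-driven
    cluster-count selection and importance pruning over random forests.
    Reconstructs single-cell copy-number profiles from genomic bin read
    counts with quality control, recursive binary segmentation, ploidy
    grid search and a concordance-based clonality caller, and predicts
    single-cell clonal status from phenotypic features after
    correlation-based feature selection. Includes a seeded synthetic
    cohort and genome generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    pROC,
    randomForest,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
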