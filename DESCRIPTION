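Package: mdrscreen
Title: Phenotypic Screening and Activity Profiling of Resistance-Selective Cytotoxic Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotype-based discovery of cytotoxic compounds that
    selectively kill multidrug-resistant cancer cells. Implements plate-level
    survival-index computation with assay quality control for fluorometric
    cytotoxicity screens, differential hit calling between a resistant cell
    line and its parent, four-parameter sigmoidal dose-response fitting with
    censored absolute IC50s and censored group medians, ex vivo activity
    indices over diagnosis-annotated patient-cell panels (response rates,
    solid/hematological ratio, normal-vs-tumor specificity), connectivity-map
    style mechanism inference from ranked expression signatures via the
    two-tail Kolmogorov-Smirnov score, preranked gene-set enrichment with a
    permutation p-value, and hollow-fiber net-growth analysis. Seeded
    synthetic-data generators with planted ground truth reproduce the
    statistical structure of each assay for validation and benchmarking.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
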