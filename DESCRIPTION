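Package: somaticsieve
Title: Tumor-Only Somatic Variant Classification by Database-Guided Decision Tree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies tumor-only variant calls as somatic or germline with a
    three-phase decision tree: quality and consequence filtration, germline
    population-database screening at a 1% minor-allele-frequency cutoff with a
    somatic-catalogue (COSMIC-style) override, and a clinical-significance
    (ClinVar-style) benign rescue. Includes reference-free variant
    normalization, VCF/TSV readers and writers, in-memory annotation against
    local population, somatic-catalogue and clinical databases, a
    matched-normal gold-standard builder with sensitivity/specificity
    evaluation, and a deterministic synthetic tumor/normal cohort generator
    with configurable database completeness and noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    yaml,
    withr,
    methods,
    stats,
    tools,
    utils,
    VariantAnnotation,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
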