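Package: proteoage
Title: Multi-Omics Analysis of Proteostasis Decline in Vertebrate Brain Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying the loss of protein
    homeostasis during vertebrate (killifish) brain aging from matched
    transcriptomic and proteomic data. Implements peptide-spectrum-match level
    TMT reporter-ion processing and protein-group summarization, an
    in-silico-digestion based iBAQ procedure, empirical-Bayes moderated
    differential abundance with Benjamini-Hochberg correction and Fisher
    p-value combination, per-sample transcript-protein correlation and
    regulatory-mechanism classification, protein-complex stoichiometry
    analysis (complex-relative normalization, affected-complex calling and
    fold-change interquartile ranges), size-exclusion-chromatography
    co-elution statistics against randomized complex nulls, SDS-insoluble
    aggregate enrichment with biophysical-property scoring, and per-gene Cox
    proportional-hazards modelling of longitudinal expression change against
    lifespan. Every stage can be exercised on synthetic cohorts with known
    ground truth generated by the package itself.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    fgsea,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
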