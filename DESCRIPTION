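Package: anaerodesign
Title: Rational Design of Facultative-Anaerobic Derivatives of Aerobic Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for designing a facultative-anaerobic
    derivative of an obligate aerobic bacterium. Combines persistence-based
    protein-domain core comparison across lifestyle-labelled genomes,
    random-forest cumulative-Gini ranking of domain architectures, a
    direction-consistency filter over condition-wise transcriptome fold
    changes, and flux-balance detection of oxygen-blocked biomass precursors,
    and integrates all evidence into a categorized gene and vitamin design
    table. A synthetic-data module generates genome annotation sets,
    transcriptome count matrices and a toy metabolic model with planted
    ground truth so the whole pipeline is testable without downloads.
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
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    xml2
Suggests:
    ape,
    DESeq2,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
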