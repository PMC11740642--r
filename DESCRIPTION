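Package: triolof
Title: Gene-to-Patient Discovery of De Novo Loss-of-Function Variants in
    Constrained Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A gene-to-patient analysis pipeline for rare-disease trio
    cohorts. Identifies de novo predicted loss-of-function (pLoF) variants
    from trio genotypes, keeps high-confidence calls via a simplified
    LOFTEE-style heuristic, applies population allele-frequency and LOEUF
    gene-constraint gates, splits retained genes into known disease genes
    versus novel contenders, classifies contenders into three evidence
    tiers by exact and organ-system-level Human Phenotype Ontology
    matching, and evaluates candidate validation against a later knowledge
    snapshot with exact contingency statistics. Ships a fully synthetic
    cohort generator (trio VCF, pedigree, constraint table, phenotype and
    ontology files, external phenotype database) with a ground-truth
    manifest so every stage is testable without restricted data.
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
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
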