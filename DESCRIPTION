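Package: ontotyper
Title: Ontology-Guided Genome-Wide Association with Hierarchical Mutation-Burden Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates non-synonymous variant calls into hierarchical
    system-level mutation-burden features ("ontotypes") by propagating binary
    gene-mutation indicators up an ontology directed acyclic graph, fits
    phenotype predictors (random forest, mixed random forest with a kinship
    random effect, GBLUP, penalized regression) under 5-fold cross-validation,
    identifies the biological systems driving prediction with response-permutation
    feature importance and an empirical false discovery rate, validates systems
    with mutation-burden ANOVA against random gene sets, and partitions
    phenotypic variance with additive and epistatic genomic relationship
    matrices. Includes a synthetic-data generator for structured haploid
    populations with planted causal systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
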