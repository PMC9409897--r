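Package: fluxprint
Title: Metabolic Footprint Integration and Constraint-Based Modelling for
    Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for enhancing genome-scale metabolic models (GSMMs) with
    exometabolome ("metabolic footprint") evidence and analysing the result.
    Provides a validated model container with gene-protein-reaction (GPR)
    expressions and a versioned JSON/TSV exchange schema, flux balance
    analysis (growth simulation on defined media and biosynthetic capability
    screening) on top of a deterministic bounded-variable simplex solver,
    reaction gap-filling against a universal candidate set, differential
    accumulated metabolite (DAM) calling from LC-MS feature-intensity tables
    (Welch tests, ANOVA with Tukey post-hoc, volcano/PCA/cluster summaries),
    overlay of DAMs and differentially expressed genes onto pathway
    subnetworks, and seeded synthetic-data generators for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    xml2,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
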