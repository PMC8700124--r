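Package: mitofunnel
Title: Temporal Candidate Prioritisation for Synaptic and Non-Synaptic
    Mitochondrial Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying mitochondrial proteins whose expression
    diverges specifically in aged synaptic mitochondria from label-free
    proteomic timecourses. Implements ANOVA-based feature and protein
    filtering on ArcSinh-transformed normalised abundances, Pearson
    correlation networks over samples and proteins, Markov clustering (MCL)
    of co-expression graphs, temporal trend classification, a cross-
    compartment subtractive candidate funnel with archetypal-profile and
    old-age fold-change filters, and supporting enrichment statistics
    (Fisher exact over-representation, Benjamini-Hochberg FDR, marker
    t-tests, activation z-scores). Includes a synthetic-data generator that
    plants labelled temporal trend classes under a two-compartment,
    three-age, replicated design so every stage can be validated against
    ground truth.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
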