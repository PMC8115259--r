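Package: dualcore
Title: Dual Taxonomic and Functional Core Rhizobiome Analysis
Version: 0.1.0
Authors@R: person("Core Rhizobiome", "Maintainers", email = "maintainers@dualcore.dev",
    role = c("aut", "cre"))
Description: Identifies the core rhizosphere microbiome of a crop along two
    complementary routes: a prevalence-based taxonomic core (ASVs present in
    at least a cut-off fraction of samples) and a functional core (ASVs
    qualified through KEGG orthologs that are themselves prevalent across
    samples, capturing functional redundancy). Includes a PICRUSt-style
    metagenome predictor driven by a user-supplied per-ASV gene copy-number
    table, beta-diversity comparison statistics (Bray-Curtis, unweighted
    UniFrac, PCoA, ANOSIM, PERMANOVA, Welch's t with Benjamini-Hochberg
    correction), a habitat-corrected co-occurrence network built on the
    maximal information coefficient (MIC) with permutation-FDR edge calling
    and centrality-based hub detection, a synthetic-data generator with
    planted ground truth, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    igraph,
    jsonlite,
    biomformat,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phyloseq,
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
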