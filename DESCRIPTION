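Package: genopred
Title: Genomic Prediction with GBLUP, BayesB and the Elastic Net
Version: 1.0.0
Authors@R: person("J.", "Keller", email = "jkeller@example.org",
    role = c("aut", "cre"))
Description: A self-contained genomic-selection toolkit for diploid SNP
    panels: quality control (call rate, minor allele frequency,
    Hardy-Weinberg equilibrium), mean imputation of sporadic missing
    genotypes, fixed-effect pre-adjustment of phenotypes, genomic
    relationship matrices, restricted maximum likelihood variance
    components by eigendecomposition, genomic best linear unbiased
    prediction (GBLUP) and its ridge-regression (RR-BLUP) dual, a BayesB
    spike-and-slab Markov chain Monte Carlo sampler, elastic-net marker
    regression by coordinate descent with cross-validated penalty
    selection, and k-fold / forward-in-time validation with Pearson and
    realized accuracy. Includes a seeded simulator of genotypes and
    additive trait architectures so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
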