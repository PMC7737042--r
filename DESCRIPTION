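Package: pairgwas
Title: Pairwise GWAS Segment Classification and Partial Genetic Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the shared genetic basis of two correlated traits from
    genome-wide association (GWAS) summary statistics. Implements a Bayesian
    pairwise-GWAS analysis that classifies approximately independent
    linkage-disequilibrium (LD) blocks as associated with one trait, with both
    traits through a shared signal, with both through separate signals, or with
    neither, using Wakefield approximate Bayes factors, regional Bayes factors,
    genome-wide empirical-Bayes model priors and a sample-overlap correction.
    Also provides LD score regression with block-jackknife standard errors for
    heritabilities and cross-trait genetic correlations, and partial genetic
    correlations of third traits with each focal trait after removing genetic
    overlap with the other, via a multiple regression on the genetic covariance
    matrix. Includes generators for synthetic two- and three-trait summary
    statistics with block LD structure, configurable causal models, polygenic
    backgrounds and sample overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
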