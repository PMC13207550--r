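Package: pestphylo
Title: Phylogenetic Comparative Analysis of Pest Invasiveness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for phylogenetic comparative analysis of binary
    invasion outcomes in species assemblages, motivated by the study of
    crop pest invasions. Provides taxonomic grafting of sequence-less
    species into a dated phylogeny, phylogenetic signal statistics for
    continuous traits (Blomberg's K, Pagel's lambda) and binary traits
    (Fritz-Purvis D with Brownian-threshold and permutation nulls),
    phylogenetically informed imputation of missing continuous traits
    under Brownian motion, lambda, Ornstein-Uhlenbeck and Early-Burst
    covariance models with AIC model selection, a Bayesian phylogenetic
    Bernoulli mixed model with MCMC diagnostics and Nakagawa variance
    decomposition, hierarchical partitioning of trait contributions, and
    synthetic-data generators that emulate the structure of a pest
    assemblage so that every stage of the pipeline can be validated
    against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
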