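Package: chickpop
Title: Population-Genomic Structure Analysis Across Replicated Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for low-coverage genotyping-by-sequencing (GBS)
    population genomics across replicated environmental gradients. Implements
    hierarchical Bayesian genotype-probability estimation from genotype
    likelihoods (Gibbs sampling with Hardy-Weinberg allele-frequency priors),
    standard SNP retention filters, Hudson-estimator F_ST and Nei's genetic
    distance with permutation nulls, PCA/DAPC ordination with PERMANOVA,
    hierarchical AMOVA with phi-statistics, multiple regression on distance
    matrices, and a permutation test for parallel locus-specific divergence
    shared across replicated high/low-elevation contrasts, together with a
    Balding-Nichols synthetic-data generator so the whole analysis is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
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
    vcfR
LinkingTo: Rcpp
Suggests:
    MASS,
    geosphere,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
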