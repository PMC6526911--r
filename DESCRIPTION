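Package: pomotree
Title: Polymorphism-Aware Species Tree Inference with Boundary Mutation
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Species tree inference from allele-frequency data under the
    discrete multivariate boundary mutation model (PoMo).  Provides the
    polymorphism-aware state space and rate matrices built from reversible
    nucleotide mutation models (JC, HKY, GTR) combined with Moran-process
    genetic drift, Gamma-distributed mutation rate heterogeneity as a
    mixture over rate matrices, leaf likelihood initialization strategies
    for allele count data (sampled, weighted binomial, weighted
    hypergeometric), Felsenstein pruning likelihoods with maximum
    likelihood estimation of branch lengths and model parameters,
    nonparametric bootstrap, AIC/BIC model ranking, a matching sequence
    simulator for validation by parameter recovery, tree comparison
    metrics, and readers and writers for the counts-file format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    Matrix,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
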