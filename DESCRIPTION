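Package: gpbound
Title: Asymptotic Accuracy and Estimability Bounds for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation study of the asymptotic behaviour of genomic
    prediction accuracy as the reference population grows. Provides a
    forward-in-time gene-dropping simulator over synthetic phased founder
    haplotypes (segment-origin tracking with crossover and mutation),
    marker/QTL selection scenarios by minor allele frequency, trait
    simulation at fixed heritability, single-site Gibbs samplers for
    whole-genome regression (BayesB, BayesC and GBLUP as BayesC with
    pi = 0), genomic relationship matrices, an estimability-based upper
    bound for the reliability of prediction obtained by projecting
    validation genotypes onto the row space of the reference genotype
    matrix, and closed-form accuracy approximations based on the
    effective number of chromosome segments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
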