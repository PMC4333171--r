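Package: gpimpute
Title: Genotype Imputation and Genome-Enabled Prediction of Complex Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for studying how genotype imputation affects
    genome-enabled prediction of complex traits in pedigreed outbred
    populations. Simulates heterogeneous-stock-like populations descended
    from inbred founder strains (gene dropping with Haldane recombination,
    family/cage confounding, configurable trait architectures), applies
    locus quality control and equally spaced low-density panel selection,
    pre-corrects phenotypes with a pedigree-based linear mixed model,
    imputes masked genotypes with a diploid Li-Stephens haplotype hidden
    Markov model, and compares three whole-genome prediction models
    (Bayesian LASSO, reproducing kernel Hilbert space regression with
    kernel averaging, and a Bayesian-regularized neural network) under
    family-structured cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Rcpp,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
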