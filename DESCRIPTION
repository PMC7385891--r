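Package: semgwas
Title: Multi-Trait Multi-Locus Structural Equation Models for
    Genotype-Phenotype Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and estimates structural equation models that relate
    SNPs, latent factors and phenotypic traits in association panels.
    Correlated traits are aggregated into latent factors (measurement
    part), factors may be causally linked in a directed acyclic graph
    (structural part), and SNPs are attached either to factors
    (pleiotropic effects) or to individual traits (single-trait effects)
    by a greedy Wishart-density selection. Ordinal traits and SNP codes
    are handled on the latent-normal scale through threshold models and
    polychoric/polyserial correlations. Parameters are estimated by
    maximum likelihood during construction and by Gibbs sampling with
    data augmentation for final inference; trait prediction is validated
    by k-fold cross-validation. A synthetic-data generator with known
    truth supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
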