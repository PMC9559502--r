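Package: herdlink
Title: Across-Herd Genetic Evaluation, Connectedness and Gene Flow for
    Pig Litter-Size Traits
Version: 0.1.0
Authors@R:
    person("herdlink", "maintainers", email = "maintainers@herdlink.dev",
           role = c("aut", "cre"))
Description: Pedigree-based genetic evaluation of litter size (number born
    alive) in multi-herd pig populations under a repeatability animal model.
    Provides pedigree validation and ordering, inbreeding via the
    Meuwissen-Luo algorithm, the numerator relationship matrix and its sparse
    inverse, sparse design matrices for the litter-size model, EM-REML
    variance components, BLUP of breeding values with exact prediction error
    variances via sparse selected inversion, connectedness ratings between
    herds from the inverse mixed-model coefficient matrix, gene-flow
    contribution matrices tracing genes to founder herds, and a configurable
    multi-herd breeding-program simulator used as the test bed for the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
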