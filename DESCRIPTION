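Package: MutLineage
Title: Single-Cell Lineage Analysis of Mutator Phenotypes and Asymmetric
    Mutation Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing replication-error counts from single-cell
    pedigrees of mutator yeast. Implements segregant-group mutation calling
    (Da/Db/Ma/Mb) from per-colony variant tables and callable intervals,
    detection of pedigree assignment errors, overdispersed count-model
    fitting and selection (Poisson mixtures by EM, negative binomial by
    profile maximum likelihood, AIC/BIC and Akaike weights), the
    gamma-Poisson equivalence of the negative binomial, and stochastic
    simulators of mutator volatility and all-or-none chromosome segregation
    (Poisson-binomial and gamma-Poisson-binomial processes) on yeast and
    human karyotypes. A synthetic-lineage generator with full ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
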