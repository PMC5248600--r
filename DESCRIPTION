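Package: mtmmGWAS
Title: Multi-Trait Mixed-Model GWAS with Factor-Analytic Covariance and
    Compressed Kinship
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-trait genome-wide association mapping for structured
    plant panels. Fits a multi-trait mixed model with a second-order
    factor-analytic genetic covariance on a compressed (cluster-averaged)
    kinship matrix, and tests per-SNP Wald hypotheses for trait-specific,
    consistent and contrasting (group-vs-group) effects. Includes
    trait derivation from raw plant observations (transformations, BLUEs,
    control correction, PC1 collapsing), marker-based heritability and
    genetic-correlation estimation with a G-BLUP fallback, regression-based
    genomic control of -log10(P) values, candidate-region post-processing
    (LD blocks, gene windows, enrichment mid-P, BH FDR), genetic-correlation
    networks, and a simulation module for power comparisons between the
    full, contrast and univariate analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'mtmm-engine.R'
    'mtmm.R'
    'association.R'
    'simulate.R'
    'postprocess.R'
    'kinship.R'
    'traits.R'
    'io.R'
    'cli.R'
    'mtmmGWAS-package.R'
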