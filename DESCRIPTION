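Package: lducoloc
Title: Colocalization of Disease and Expression QTL on Linkage
    Disequilibrium Unit Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate effector genes of disease risk loci by
    co-locating causal-variant location estimates for disease and for gene
    expression (eQTL) on metric linkage-disequilibrium-unit (LDU) genetic
    maps, and validates the resulting cis-genes with independent expression
    data. Provides coordinate algebra on LDU maps (interpolation, inversion
    of +/- 1 LDU windows), replication clustering of disease location
    estimates, 1-LDU co-location calls, cis-gene assignment within a
    physical window, nuclear-encoded mitochondrial gene (NEMG) flagging,
    per-gene differential-expression Z-scores from probe-level data (mixed
    models), DerSimonian-Laird random-effects meta-analysis across studies,
    competitive gene-set enrichment with gene-sampling permutation nulls,
    a correlation-stratified NEMG regression with a robust outlier
    procedure, count-based pathway enrichment with random and structured
    (locus-clustered) permutation nulls, seeded synthetic-data generators
    with planted ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    lme4,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
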