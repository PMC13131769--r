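Package: snqtl
Title: Four-Tier Causal Prioritization of Cell-Type cis-eQTLs at GWAS Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-nucleus pseudobulk cis-eQTL mapping with multi-dataset
    meta-analysis (fixed-effects, DerSimonian-Laird random-effects, and the
    Han-Eskin RE2 likelihood-ratio model), Bayesian colocalization with
    Wakefield approximate Bayes factors, summary-based Mendelian randomization
    with the HEIDI heterogeneity test, beta-binomial single-nucleus
    allele-specific expression testing, genotype-by-pathology dynamic eQTLs,
    LD clumping into independent signal chunks, and the four-tier integration
    that prioritizes candidate causal risk genes for GWAS loci per cell type.
    Includes a synthetic-cohort generator (LD-structured genotypes,
    negative-binomial single-cell counts with planted cis effects, LD-aware
    GWAS summary statistics, beta-binomial phased allele counts) that provides
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    metafor,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
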