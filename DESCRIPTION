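Package: riskeqtl
Title: Two-Stage cis-eQTL Mapping and LD-Based Candidate Gene
    Classification at GWAS Risk Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps expression quantitative trait loci (eQTL) at GWAS risk
    loci in bulk RNA-seq cohorts using a two-stage design: a primary scan
    of risk variants and their linkage-disequilibrium (LD) companions
    against all genes within 1.1 Mb, followed by a gene-based scan of all
    variants around significant target genes. Provides variant and gene
    quality control, depth- and GC-aware expression normalization,
    covariate adjustment with expression principal components, risk-region
    and risk-locus construction from a published variant list, a
    covariate-residualized matrix association engine, gene-centric
    hierarchical false discovery rate control per gene class, and
    classification of candidate genes into Groups 1-3 by LD between the
    peak eQTL variant and the risk variant. Includes a seeded synthetic
    cohort generator (founder-haplotype LD blocks, negative-binomial
    counts with GC and depth bias, cell-fraction covariates) so the whole
    pipeline is testable without access to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    IRanges,
    jsonlite,
    rlang,
    S4Vectors,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
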