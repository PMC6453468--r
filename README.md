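# riskeqtl

Two-stage cis-eQTL mapping and LD-based candidate-gene classification at
GWAS risk loci.

## The problem

Genome-wide association studies flag risk variants, but most sit in
non-coding sequence and act — if they act at all — by modulating the
expression of nearby genes, often through linkage disequilibrium (LD)
with an untyped causal variant. Expression quantitative trait locus
(eQTL) analysis in the disease-relevant normal tissue links each risk
variant to the genes whose expression tracks its allele dosage, turning
an anonymous association signal into a ranked list of candidate genes.
`riskeqtl` implements that workflow for a bulk RNA-seq cohort with
genome-wide genotypes and a published risk-variant list, including a
seeded synthetic-cohort generator so the whole pipeline can be
exercised, calibrated, and tested without access to protected human
data.

## The method

**Risk loci.** Each risk variant that survives intake screening (present
in the genotypes, MAF ≥ 1%, not in perfect LD with an earlier-listed
risk variant) is surrounded by a ±100 kb *risk region*; overlapping
regions merge. Within a region, risk variants with pairwise r² ≥ 0.5 are
clustered (single linkage) into one *risk locus*, and the locus is
expanded to every region variant with r² ≥ 0.5 to any of its risk
variants.

**Stage 1 — variant-based scan.** Every locus variant is tested against
every expressed gene whose span lies within ±1.1 Mb, under an additive
linear model adjusted for covariates (lymphocyte and epithelial cell
fractions plus expression principal components, each explaining > 1% of
variance). Covariates are projected out of expression and dosage
matrices once; the per-pair statistic is then the correlation of
residuals, with

    t = r · sqrt(df / (1 − r²)),   df = n − 2 − #covariates,

which reproduces the full multiple-regression t-statistic exactly
(Frisch–Waugh–Lovell).

**Gene-centric FDR.** Per gene, the minimum p is Bonferroni-adjusted by
that gene's own test count; across genes, Benjamini–Hochberg q-values
are computed separately within each gene class (protein-coding, lncRNA,
other), and genes with q ≤ 1% are declared gene-wise significant.

**Stage 2 — gene-based scan.** All QC-passing variants within ±1.1 Mb
of each significant gene's TSS/TES are tested against it, with a pooled
variant-level BH pass across all target genes.

**Classification.** Each significant gene's *peak eQTL variant* (minimum
p over both stages) is compared with the risk variant(s) of each locus
that scanned the gene: r² ≥ 0.5 → **Group 1** (the gene is a strong
candidate effector of the risk variant), r² ∈ [0.2, 0.5) → **Group 2**,
r² < 0.2 → **Group 3** (likely a tissue eQTL unrelated to the risk
signal). A gene near several loci gets one call per locus and is counted
once, at its highest-LD group, in summary tables.

Upstream of all this sit the standard QC steps: variant call-rate ≥ 95%,
exact Hardy–Weinberg p ≥ 1e-5, MAF ≥ 1% (allelic-r² ≥ 0.3 for imputed
dosages); a median-raw-count ≥ 8 gene filter with X/Y duplicate
resolution; and log2-CPM normalization with a running-median GC
correction.

## Worked example

The `analysis/` directory is a numbered workflow over the package:

```sh
Rscript analysis/01_simulate_cohort.R    # synthetic cohort -> scratch/cohort/
Rscript analysis/02_qc_normalize.R       # QC + normalization tables
Rscript analysis/03_risk_loci.R          # locus catalog
Rscript analysis/04_run_pipeline.R       # the full two-stage scan
Rscript analysis/05_regional_tables.R    # per-gene regional plot tables
```

Step 01 simulates 471 samples, 12 founder-haplotype LD blocks (120
variants), and 150 genes with three planted cis effects; one of them is
tagged by *both* a linked (same-block, r² ≈ 0.8) and an unlinked risk
variant, the configuration that produces multi-group calls in real data.
Step 04 then prints:

```
  471 shared samples; 120 variants; 150 genes
  variant QC: 120 in -> 120 out (0 excluded)
  gene filter: 150 in -> 150 out
  covariates: 2 cell fractions + 5 expression PCs (cum. 9.7% var)
  risk variants: 5 listed -> 4 included (1 excluded)
  loci: 4 regions -> 4 loci, 7 LD variants total
  stage 1: 208 tests over 7 variants x 103 genes
  gene-wise significance: 3 of 103 genes at q <= 0.01
  stage 2: 60 tests over 3 target genes
  classification: 4 (locus, gene) calls; 3 unique genes

   locus_id   gene_id     gene_class peak_variant_id       peak_p   r2_to_risk group
1 locus_001 gene_0007         lncRNA       snp_02_01 3.577724e-29 1.000000e+00     1
2 locus_002 gene_0062          other       snp_06_04 6.437828e-09 1.927857e-05     3
3 locus_003 gene_0062          other       snp_06_04 6.437828e-09 5.486686e-01     1
4 locus_004 gene_0121 protein_coding       snp_09_07 2.392567e-14 5.199410e-01     1
```

Reading the calls: all three planted genes are recovered as gene-wise
significant. `gene_0007`'s peak *is* its risk variant (r² = 1, Group 1).
`gene_0062` sits near two loci: against the linked tag the peak reaches
r² = 0.55 (Group 1), against the unlinked tag r² ≈ 0 (Group 3) — one
gene, two calls, counted once (Group 1) in the summary. Every pipeline
table (locus catalog, stage-wise associations, gene significance, group
calls, exclusion logs, JSON summary) is written under `results/run/`
with `#`-prefixed provenance headers; rerunning an identical
configuration reproduces the tables byte for byte.

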