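---
title: "Methods: two-stage cis-eQTL mapping at risk loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage cis-eQTL mapping at risk loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical model, the
choices made where the design was genuinely open, and what the synthetic
cohort does and does not establish about behaviour on real data.

# The model

## Association engine

For gene $g$ and variant $v$, the working model is additive in allele
dosage $d_v \in [0,2]$:

$$ y_g = \alpha + \beta_{gv}\, d_v + \Gamma' C + \varepsilon, $$

with $C$ the covariate vector (two histologic cell fractions and $k$
expression principal components) and $y_g$ the normalized expression.
Rather than fitting one regression per pair, `residualize()` projects
the covariate column space (intercept included) out of the expression
and dosage matrices once, and `associate()` computes, per pair, the
correlation $r$ of the two residual rows and

$$ t = r\sqrt{\frac{\mathrm{df}}{1-r^2}}, \qquad
   \mathrm{df} = n - 2 - k_{\mathrm{cov}}, $$

with a two-sided p-value from the $t_{\mathrm{df}}$ distribution and
$\beta$ recovered from the bivariate fit on residuals. By the
Frisch–Waugh–Lovell theorem this reproduces the full multiple-regression
statistics exactly; the test suite checks agreement with `lm()` fits to
$10^{-8}$ on a thousand random pairs, and this equivalence is the
module's central correctness oracle. The degrees of freedom count the
slope, the intercept, and every covariate column — the convention of
matrix-based eQTL engines.

Dosages are used as-is (fractional values from imputation are allowed;
the model is additive in expected allele count). Missing dosages are
mean-imputed per variant *after* QC so that the matrix algebra stays
exact; with call rates above 95% this perturbs statistics negligibly.
Chromosome X is treated like the autosomes: the dosage scale is
inherited from the input, which is appropriate for a single-sex cohort.

## Two stages, one peak

Stage 1 pairs every LD variant of every risk locus with every expressed
gene whose [TSS, TES] span lies within 1.1 Mb of the variant (distance
to the nearest span edge, boundaries inclusive — the most inclusive
reading of "genes within 1.1 Mb"). Stage 2 pairs each gene-wise
significant gene with every QC-passing variant in
$[\mathrm{TSS}-1.1\,\mathrm{Mb},\ \mathrm{TES}+1.1\,\mathrm{Mb}]$.
The *peak eQTL variant* of a gene is the minimum-p variant across both
stages, with a deterministic tie-break (larger $|t|$, then smaller
genomic position).

## Hierarchical, class-wise FDR

Stage-1 inference is gene-centric: each gene's minimum p-value is
Bonferroni-adjusted by that gene's own number of tests, then
Benjamini–Hochberg q-values are computed over these adjusted minima,
*separately within each gene class* (protein-coding, lncRNA, other),
and genes with $q \le 0.01$ are significant. Class separation matters:
lncRNA signals would otherwise be swamped by the much larger
protein-coding ensemble. The FDR procedure is plain BH step-up — the
minimal-assumption choice for "q-values" computed on adjusted minima —
delegated to `stats::p.adjust(method = "BH")` and verified against a
brute-force step-up oracle in the tests. Stage 2 uses one pooled BH
pass across all (gene, variant) records of the significant genes.

## LD, loci, classification

LD is genotypic $r^2$: the squared Pearson correlation of dosage
vectors, invariant to allele flips — the convention of PLINK's
`--r2` on dosage data, and the right scale for tag-SNP arguments.
Risk regions are ±100 kb intervals around included risk variants,
merged transitively on true overlap (shared ≥ 1 bp; coordinates 1-based
inclusive). Within a region, risk variants are clustered into loci by
single linkage at $r^2 \ge 0.5$ — the weakest assumption consistent
with treating variants "in LD" as one locus — and a locus's variant set
contains every region variant reaching $r^2 \ge 0.5$ to *any* of its
risk variants (the "any" reading keeps the set monotone in the
threshold and matches testing all variants of a locus).

Classification compares the gene's peak variant with the locus's risk
variants and takes the **maximum** $r^2$ when a locus carries several —
the Group-promoting reading; the anchor is recorded per call. Group
boundaries are inclusive on the left: $r^2 = 0.5$ is Group 1,
$r^2 = 0.2$ is Group 2. A gene scanned by several loci receives one
call per locus; unique-gene summaries count it once at its
highest-LD group.

Intake screening of the published risk list applies, in order: presence
in the genotype file, MAF ≥ 1%, and perfect-LD deduplication
($r^2 > 1 - 10^{-9}$) keeping the first-listed variant — deterministic
and auditable.

# Normalization and covariates

Counts are filtered (median raw count ≥ 8 across samples, boundary
retained, after resolving X/Y annotation duplicates in favour of the X
record) and normalized as
$\log_2(\mathrm{count}+0.5) - \log_2(\mathrm{depth}/10^6)$, followed by
a cross-gene GC correction: per-gene mean log2-CPM is ordered by GC
fraction, smoothed by a running median (window 31 genes or the largest
odd window the panel allows), and the centered smooth is subtracted
from each gene's row. This removes the two systematic biases —
sequencing depth and GC content — that conditional-quantile-style
normalization targets, at the cost of modelling the GC effect as a
single per-gene offset rather than a quantile-specific curve. That is a
deliberate simplification: it preserves within-gene sample ranking, is
permutation-equivariant, and is sufficient for dosage-association
inference, which is invariant to per-gene location shifts. It does not
reproduce quantile-specific distortions of the expression distribution,
and analyses that depend on cross-gene expression magnitudes should use
a full conditional quantile normalization instead.

Covariates are the lymphocyte and epithelial cell-fraction percentages
plus expression principal components. PCs are computed on gene-centered
normalized values, and every component explaining more than 1% of total
variance is retained, up to an optional cap `max_pcs`. The 1% rule is
intentionally data-dependent (on a transcriptome-wide matrix it yields
on the order of a dozen components; source reports of such analyses
disagree with themselves on the exact count, which is one reason the
package parameterizes it). **The cap matters for small panels**: on a
synthetic panel of 100–600 genes, the spectrum of a pure-noise matrix
concentrates near $1/\min(n,p)$, dozens of noise PCs clear 1%, and a
PC can align with a single strong cis effect and absorb it. The
simulation studies therefore run with `max_pcs = 5`, chosen once as a
realistic latent dimension for a cohort with a handful of technical
factors; the threshold rule itself is unchanged.

# The synthetic cohort

The generator exists so that every downstream stage is testable
offline; it emulates the *statistical structure* the analysis assumes,
not human genetics.

* **Genotypes** are founder-haplotype copies: each LD block draws $k$
  founder haplotypes (binary patterns over the block's SNPs, per-SNP
  founder allele frequency uniform on [0.2, 0.8]); each sample draws
  two founders per block independently. This yields hard HWE calls by
  construction, elevated within-block LD that decreases in $k$
  ($k = 2$ forces $r^2 = 1$), near-zero cross-block LD, and a
  rejection-resampling MAF floor (default 5%) with a loud failure when
  the configuration cannot reach it. There is no recombination within
  blocks, no mutation, and no attempt to mimic real LD maps or MAF
  spectra.
* **Counts** are negative binomial with a log-link mean combining a
  per-gene baseline (log2 mean uniform on [4, 10]), a linear GC term,
  cell-fraction effects, a log-normal library-depth factor
  ($\sigma = 0.25$), and the planted dosage effects
  (overdispersion $\phi = 0.02$, i.e. a biological CV of about 14%).
  Planted effect sizes are *standardized*: `beta` is in units of the
  residual s.d. of log2 expression, converted internally via the
  delta-method approximation
  $\mathrm{sd} \approx \sqrt{1/\mu + \phi}/\ln 2$ at the gene's
  baseline mean, so a "0.6 s.d. per allele" effect means the same
  thing across genes of different depth.
* **Defaults** mirror the shape of a normal-prostate eQTL cohort: 471
  samples, lymphocyte fraction ≤ 2%, epithelial fraction 40–90%, an
  effect size of 0.6 s.d./allele, and tag variants drawn either from
  the causal variant's own block (realized $r^2$ targeted at 0.8,
  accepted within [0.6, 0.95]) or from an unlinked block. All
  randomness flows from one seed with fixed per-stage offsets, so
  fixtures are byte-stable.

## What the simulations establish — and what they don't

Under these conditions the test suite shows: exact agreement of the
association engine with per-pair regression; uniform null p-values and
nominal 5% type-I error; per-class gene-wise discovery at or below the
nominal 1% FDR on fully null cohorts (50 seeds × 600 genes, n = 400);
and ≥ 90% recovery (observed ≈ 98%) of a planted 0.6 s.d. effect as a
Group-1 call through its linked tag and as a Group-3 call through an
unlinked tag over 100 replicate cohorts. A note on the Group-3 design:
a gene can only be classified after passing stage 1, and a lone
unlinked risk variant cannot make it significant; the scenario
therefore plants one causal variant inside the cis windows of *two*
risk variants — one linked, one unlinked — which is exactly how
multi-group calls arise in real data (genes near several loci).

These results validate the machinery, not the biology: real cohorts
have long-range and irregular LD, MAF- and length-dependent expression
noise, batch structure that is not low-rank, cell-type mixtures beyond
two fractions, and eQTL architectures with multiple causal variants per
gene. Passing the synthetic suite says the pipeline computes the
intended quantities correctly and controls error under its own
assumptions; it does not certify discovery rates on any real dataset.

# Numerical and degenerate-input policy

* Exact HWE p-values are computed by log-space enumeration of
  heterozygote configurations conditional on allele counts, summing
  probabilities ≤ the observed one (with a $1+10^{-9}$ tie guard);
  monomorphic variants return p = 1. The test suite checks all
  genotype triples with total ≤ 50 against an independent
  recurrence-based oracle.
* Rank-deficient covariate designs fail, naming the collinear columns;
  residual correlations are clamped to $[-1, 1]$; pairs whose genotype
  residual has (numerically) zero variance are flagged and carry no
  p-value; genes with no valid stage-1 test are excluded and logged.
* Ties at the peak break by $|t|$ then position; perfect-LD screening
  keeps the first-listed risk variant; regions merge only on true
  overlap (adjacency is not overlap).
* Problem sizes in the simulation studies — 1,000 oracle pairs, 50
  null seeds of 600 genes, 100 recovery replicates at n = 400, 200
  peak-recovery draws — were chosen as the smallest sizes at which the
  Monte-Carlo error of each calibration quantity is well below its
  acceptance margin.

# Known limitations

* The GC correction is a per-gene offset, not quantile-specific; see
  above.
* Trans-eQTLs, isoform-level effects, conditional/secondary signals,
  Storey q-values, and permutation-based FDR are out of scope.
* The generator's LD is block-diagonal; analyses that depend on LD
  decay with distance (e.g. fine-mapping resolution) cannot be studied
  with it.
* The locus catalog and gene lists of any particular published study
  are reproducible only with that study's genotype and expression
  data; the package reproduces the *procedure* and its printed
  arithmetic, not the catalog.
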