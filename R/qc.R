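#' Exact Hardy-Weinberg equilibrium p-value
#'
#' Exact test on genotype counts: conditional on the observed allele
#' counts, heterozygote counts are enumerated, their probabilities under
#' random mating computed in log space, and the p-value is the summed
#' probability of all configurations no more probable than the observed
#' one. Symmetric under allele relabeling. A monomorphic variant admits a
#' single configuration, so p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative; total > 0).
#' @return p-value in (0, 1\].
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)            # monomorphic
  rare <- min(nA, na)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((na - hets) / 2 + 1) +
    hets * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}

# per-variant QC summaries on a dosage matrix (samples x variants)
.variant_qc_stats <- function(dosages) {
  called <- colSums(!is.na(dosages))
  call_rate <- called / nrow(dosages)
  p_alt <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  list(call_rate = call_rate, maf = maf)
}

#' Variant quality control
#'
#' Genotyped variants must pass, in order: call rate >= `call_rate_min`,
#' exact Hardy-Weinberg p >= `hwe_p_min` (computed on dosages rounded to
#' hard genotypes, called samples only), and MAF >= `maf_min`. Imputed
#' variants must pass, in order: allelic r-squared >= `allelic_r2_min`
#' and MAF >= `maf_min`. Each dropped variant is logged with the first
#' failing rule. The operation is idempotent.
#'
#' @param geno a [genotype_matrix()].
#' @param call_rate_min,hwe_p_min,maf_min,allelic_r2_min thresholds; the
#'   defaults are the conventional array-QC settings (95% call rate,
#'   HWE p 1e-5, 1% MAF, imputation allelic r-squared 0.3).
#' @return list: `geno` (retained variants), `exclusions` (data.frame
#'   `variant_id`, `reason` with reasons in
#'   \{call_rate, hwe, maf, allelic_r2\}).
#' @export
filter_variants <- function(geno, call_rate_min = 0.95, hwe_p_min = 1e-5,
                            maf_min = 0.01, allelic_r2_min = 0.3) {
  stopifnot(inherits(geno, "genotype_matrix"))
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            maf_min >= 0, maf_min < 0.5,
            allelic_r2_min >= 0, allelic_r2_min <= 1)
  st <- .variant_qc_stats(geno$dosages)
  imputed <- geno$variants$is_imputed
  reason <- rep(NA_character_, n_variants(geno))

  # genotyped: call rate, then HWE, then MAF
  gi <- which(!imputed)
  reason[gi[st$call_rate[gi] < call_rate_min]] <- "call_rate"
  for (j in gi) {
    if (!is.na(reason[j])) next
    g <- round(geno$dosages[, j])
    g <- g[!is.na(g)]
    p <- hwe_exact_pvalue(sum(g == 0), sum(g == 1), sum(g == 2))
    if (p < hwe_p_min) reason[j] <- "hwe"
  }
  need_maf <- gi[is.na(reason[gi])]
  reason[need_maf[st$maf[need_maf] < maf_min]] <- "maf"

  # imputed: allelic r2, then MAF
  ii <- which(imputed)
  r2 <- geno$variants$allelic_r2[ii]
  reason[ii[!is.na(r2) & r2 < allelic_r2_min]] <- "allelic_r2"
  ii2 <- ii[is.na(reason[ii])]
  reason[ii2[st$maf[ii2] < maf_min]] <- "maf"

  drop <- !is.na(reason)
  list(geno = genotype_matrix(geno$dosages[, !drop, drop = FALSE],
                              geno$variants[!drop, , drop = FALSE]),
       exclusions = data.frame(variant_id = geno$variants$id[drop],
                               reason = reason[drop],
                               stringsAsFactors = FALSE))
}

#' Mean-impute missing dosages
#'
#' Replaces `NA` dosages by the per-variant mean of called samples,
#' keeping the matrix algebra of the association engine exact. Applied
#' after QC, before association.
#'
#' @param geno a [genotype_matrix()].
#' @return the genotype matrix with no missing dosages.
#' @export
impute_missing_dosages <- function(geno) {
  d <- geno$dosages
  nas <- which(is.na(d), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(d, na.rm = TRUE)
    d[nas] <- mu[nas[, 2]]
    geno$dosages <- d
  }
  geno
}

#' Gene filtering
#'
#' Resolves X/Y annotation duplicates first (a gene ID annotated on both
#' chromosomes X and Y keeps only its chromosome X record), then drops
#' genes whose median raw count across samples is below `median_min`
#' (the boundary itself is retained).
#'
#' @param expr an [expression_matrix()] with raw counts.
#' @param median_min minimum retained median raw count (default 8).
#' @return the filtered [expression_matrix()].
#' @export
filter_genes <- function(expr, median_min = 8) {
  stopifnot(inherits(expr, "expression_matrix"))
  genes <- expr$genes
  counts <- expr$counts
  is_x <- genes$chrom %in% c("X", "chrX")
  is_y <- genes$chrom %in% c("Y", "chrY")
  dup <- intersect(genes$gene_id[is_x], genes$gene_id[is_y])
  if (length(dup)) {
    drop <- genes$gene_id %in% dup & is_y
    genes <- genes[!drop, , drop = FALSE]
    counts <- counts[!drop, , drop = FALSE]
  }
  med <- apply(counts, 1, median)
  keep <- med >= median_min
  if (!any(keep)) stop("no genes pass the median raw count filter")
  expression_matrix(counts[keep, , drop = FALSE],
                    genes[keep, , drop = FALSE])
}

#' Normalize expression for depth and GC content
#'
#' Per-gene log2 counts-per-million: `log2(count + 0.5) -
#' log2(depth / 1e6)` with depth the per-sample raw count total, followed
#' (optionally) by a smooth cross-gene GC correction: per-gene mean
#' log2-CPM is ordered by GC fraction, smoothed with a running median,
#' and the centered smooth is subtracted from each gene's row. This
#' removes the two systematic biases — sequencing depth and GC content —
#' that conditional-quantile-style normalization targets, with a single
#' monotone-preserving offset per sample and per gene.
#'
#' @param expr a filtered [expression_matrix()].
#' @param gc_correct apply the GC running-median correction.
#' @return the [expression_matrix()] with `normalized` filled.
#' @export
normalize_expression <- function(expr, gc_correct = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  counts <- expr$counts
  depth <- colSums(counts)
  if (any(depth <= 0)) stop("sample(s) with zero total counts")
  norm <- log2(counts + 0.5) -
    matrix(log2(depth / 1e6), nrow(counts), ncol(counts), byrow = TRUE)
  if (gc_correct) {
    gc <- expr$genes$gc_fraction
    if (anyNA(gc))
      stop("gc_fraction missing for gene(s): ",
           paste(head(expr$genes$gene_id[is.na(gc)], 5), collapse = ", "))
    if (nrow(counts) >= 5) {
      ord <- order(gc)
      gmean <- rowMeans(norm)
      k <- min(31L, nrow(counts) - 1L + nrow(counts) %% 2L)
      if (k %% 2L == 0L) k <- k - 1L
      k <- max(k, 3L)
      smooth <- runmed(gmean[ord], k, endrule = "median")
      gc_effect <- numeric(nrow(counts))
      gc_effect[ord] <- smooth - mean(smooth)
      norm <- norm - gc_effect
    }
  }
  if (!all(is.finite(norm))) stop("non-finite normalized values produced")
  expression_matrix(counts, expr$genes, normalized = norm)
}

#' Expression principal components for covariate adjustment
#'
#' Genes are centered, samples decomposed by PCA, and every component
#' explaining more than `var_explained_min` of total variance is
#' returned (up to `max_pcs`). These sample-level scores absorb latent
#' technical and compositional structure in the expression matrix.
#'
#' @param expr an [expression_matrix()] with `normalized` filled.
#' @param var_explained_min minimum per-PC variance fraction (default 1%).
#' @param max_pcs optional cap on the number of returned components.
#' @return list: `scores` (sample x PC matrix, columns `PC1`, ...),
#'   `var_explained` (per-PC fractions, non-increasing), `cumulative`
#'   (their sum).
#' @export
compute_expression_pcs <- function(expr, var_explained_min = 0.01,
                                   max_pcs = Inf) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(expr$normalized)) stop("normalize_expression() first")
  if (ncol(expr$normalized) < 2) stop("need at least 2 samples for PCA")
  pc <- prcomp(t(expr$normalized), center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- sum(frac > var_explained_min)
  k <- min(k, max_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  list(scores = scores,
       var_explained = frac[seq_len(k)],
       cumulative = sum(frac[seq_len(k)]))
}

#' Assemble the covariate design for association
#'
#' Column-binds the histologic cell fractions with the retained
#' expression PCs, aligned on sample ID.
#'
#' @param covariates data.frame with `sample_id`, `lymphocyte_pct`,
#'   `epithelial_pct`.
#' @param pcs result of [compute_expression_pcs()], or `NULL`.
#' @param sample_ids sample order of the matrices under analysis.
#' @return numeric matrix (samples x covariates) without intercept.
#' @export
assemble_covariates <- function(covariates, pcs = NULL, sample_ids) {
  idx <- match(sample_ids, covariates$sample_id)
  if (anyNA(idx)) stop("covariates missing for sample(s): ",
                       paste(head(sample_ids[is.na(idx)], 5), collapse = ", "))
  X <- cbind(lymphocyte_pct = covariates$lymphocyte_pct[idx],
             epithelial_pct = covariates$epithelial_pct[idx])
  if (!is.null(pcs) && ncol(pcs$scores) > 0) {
    sc <- pcs$scores
    if (!is.null(rownames(sc))) sc <- sc[sample_ids, , drop = FALSE]
    X <- cbind(X, sc)
  }
  rownames(X) <- sample_ids
  X
}
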