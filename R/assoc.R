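#' Project covariates out of a unit x sample matrix
#'
#' Ordinary least-squares residualization of every row of `m` on the
#' covariate design (intercept prepended). After this step, row-wise
#' correlations between two residualized matrices reproduce the
#' t-statistics of the full covariate-adjusted regression
#' (Frisch-Waugh-Lovell), which is what [associate()] exploits.
#'
#' @param m numeric matrix, units (genes or variants) in rows, samples in
#'   columns.
#' @param covariates numeric matrix (samples x covariates) or `NULL` for
#'   intercept-only residualization (row centering).
#' @return matrix of residuals, same shape as `m`; every row has mean 0
#'   and is orthogonal to each covariate column.
#' @export
residualize <- function(m, covariates = NULL) {
  stopifnot(is.matrix(m))
  design <- cbind(`(intercept)` = rep(1, ncol(m)), covariates)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Q <- qr.Q(qrd)
  m - (m %*% Q) %*% t(Q)
}

#' Additive-model association on residualized matrices
#'
#' For each (gene, variant) pair the statistic is the Pearson correlation
#' `r` of the two residual rows, converted to
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - n_covariates`
#' (slope, intercept, and the covariates projected out upstream), a
#' two-sided p-value from the t distribution, and the slope
#' `beta = sum(y * g) / sum(g^2)` of the equivalent bivariate fit on
#' residuals — i.e. expression change per alternate allele. Pairs whose
#' genotype residual has zero variance are flagged and carry no p-value.
#'
#' @param expr_resid residualized expression matrix (genes x samples).
#' @param geno_resid residualized dosage matrix (variants x samples),
#'   same samples in the same order.
#' @param pairs data.frame with `gene_id`, `variant_id`, optional
#'   `locus_id`, and `stage` (1 or 2); duplicate (gene, variant) entries
#'   are computed once and replicated back.
#' @param n_covariates number of covariate columns projected out (not
#'   counting the intercept).
#' @return data.frame: `gene_id`, `variant_id`, `locus_id`, `stage`,
#'   `beta`, `t_stat`, `p_value`, `n_used`, `flag` (`NA` or
#'   `zero_variance`).
#' @export
associate <- function(expr_resid, geno_resid, pairs, n_covariates) {
  stopifnot(is.matrix(expr_resid), is.matrix(geno_resid),
            ncol(expr_resid) == ncol(geno_resid))
  n <- ncol(expr_resid)
  df <- n - 2 - n_covariates
  if (df < 1) stop("non-positive degrees of freedom")
  if (is.null(pairs$locus_id)) pairs$locus_id <- NA_character_
  key <- paste(pairs$gene_id, pairs$variant_id, sep = "\r")
  upairs <- pairs[!duplicated(key), c("gene_id", "variant_id")]
  g_ss <- rowSums(geno_resid^2)
  e_ss <- rowSums(expr_resid^2)
  res <- vector("list", length(unique(upairs$gene_id)))
  i <- 0L
  for (gid in unique(upairs$gene_id)) {
    vids <- upairs$variant_id[upairs$gene_id == gid]
    y <- expr_resid[gid, ]
    vi <- match(vids, rownames(geno_resid))
    if (anyNA(vi)) stop("variant(s) missing from dosage matrix: ",
                        paste(vids[is.na(vi)], collapse = ", "))
    G <- geno_resid[vi, , drop = FALSE]
    xy <- as.vector(G %*% y)
    gss <- g_ss[vi]
    yss <- e_ss[gid]
    zero <- gss <= .Machine$double.eps * n | yss <= .Machine$double.eps * n
    r <- ifelse(zero, NA_real_, xy / sqrt(gss * yss))
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    pv <- 2 * pt(-abs(tt), df)
    beta <- ifelse(zero, NA_real_, xy / gss)
    i <- i + 1L
    res[[i]] <- data.frame(gene_id = gid, variant_id = vids,
                           beta = beta, t_stat = tt, p_value = pv,
                           n_used = n,
                           flag = ifelse(zero, "zero_variance",
                                         NA_character_),
                           stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, res)
  skey <- paste(stats$gene_id, stats$variant_id, sep = "\r")
  out <- cbind(pairs[, c("gene_id", "variant_id", "locus_id", "stage")],
               stats[match(key, skey),
                     c("beta", "t_stat", "p_value", "n_used", "flag")])
  rownames(out) <- NULL
  out
}

# distance from a position to a [start, end] span; 0 inside
.span_distance <- function(pos, start, end) {
  pmax(0, pmax(start - pos, pos - end))
}

#' Stage-1 cis pairs: locus variants x nearby genes
#'
#' For every LD variant of every locus, every expressed gene whose
#' \[TSS, TES\] span lies within `cis_window` of the variant (distance to
#' the nearest span edge, boundary inclusive, same chromosome) is
#' eligible. Pairs are unique per (locus, gene, variant).
#'
#' @param loci list from [build_loci()].
#' @param genes gene annotation data.frame (filtered genes).
#' @param cis_window window in bp (default 1.1 Mb).
#' @return data.frame: `gene_id`, `variant_id`, `locus_id`, `stage` = 1.
#' @export
stage1_pairs <- function(loci, genes, cis_window = 1.1e6) {
  out <- list(); i <- 0L
  for (loc in loci) {
    if (!length(loc$ld_variants)) next
    g <- genes[genes$chrom == loc$chrom, , drop = FALSE]
    if (!nrow(g)) next
    for (vid in loc$ld_variants) {
      vpos <- loc$ld_positions[[vid]]
      if (is.null(vpos)) vpos <- NA_real_
      out_rows <- g[.span_distance(vpos, g$tss, g$tes) <= cis_window, ,
                    drop = FALSE]
      if (!nrow(out_rows)) next
      i <- i + 1L
      out[[i]] <- data.frame(gene_id = out_rows$gene_id, variant_id = vid,
                             locus_id = loc$locus_id, stage = 1L,
                             stringsAsFactors = FALSE)
    }
  }
  if (!i) return(data.frame(gene_id = character(), variant_id = character(),
                            locus_id = character(), stage = integer(),
                            stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("gene_id", "variant_id", "locus_id")]), ,
      drop = FALSE]
}

#' Attach variant positions to loci
#'
#' [stage1_pairs()] needs variant coordinates; this helper annotates each
#' locus with a named position lookup for its LD variants.
#'
#' @param loci list from [build_loci()].
#' @param geno the [genotype_matrix()] the loci were built from.
#' @return the loci list with `ld_positions` added per locus.
#' @export
annotate_locus_positions <- function(loci, geno) {
  v <- geno$variants
  lapply(loci, function(loc) {
    loc$ld_positions <- as.list(setNames(
      v$pos[match(loc$ld_variants, v$id)], loc$ld_variants))
    loc
  })
}

#' Stage-2 cis pairs: all variants around target genes
#'
#' For each target gene, every QC-passing variant with position in
#' \[TSS - `cis_window`, TES + `cis_window`\] (boundaries inclusive, same
#' chromosome) is paired with the gene.
#'
#' @param target_genes annotation rows of the stage-1 significant genes.
#' @param geno the QC'd [genotype_matrix()].
#' @param cis_window window in bp (default 1.1 Mb).
#' @return data.frame: `gene_id`, `variant_id`, `locus_id` = `NA`,
#'   `stage` = 2.
#' @export
stage2_pairs <- function(target_genes, geno, cis_window = 1.1e6) {
  v <- geno$variants
  out <- list(); i <- 0L
  for (gi in seq_len(nrow(target_genes))) {
    g <- target_genes[gi, ]
    hit <- v$chrom == g$chrom & v$pos >= g$tss - cis_window &
      v$pos <= g$tes + cis_window
    if (!any(hit)) next
    i <- i + 1L
    out[[i]] <- data.frame(gene_id = g$gene_id, variant_id = v$id[hit],
                           locus_id = NA_character_, stage = 2L,
                           stringsAsFactors = FALSE)
  }
  if (!i) return(data.frame(gene_id = character(), variant_id = character(),
                            locus_id = character(), stage = integer(),
                            stringsAsFactors = FALSE))
  do.call(rbind, out)
}
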