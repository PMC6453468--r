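#' Benjamini-Hochberg q-values
#'
#' Step-up FDR q-values with monotonicity enforcement; order-preserving
#' under permutation of the input.
#'
#' @param p vector of p-values in (0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Gene-centric hierarchical significance (stage 1)
#'
#' Per gene, a Bonferroni adjustment over that gene's own tests
#' (`bonferroni_min_p = min(1, n_tests * min_p)`); then, separately
#' within each gene class, Benjamini-Hochberg q-values over the genes'
#' Bonferroni-adjusted minima. A gene is gene-wise significant when its
#' q-value is at most `q_max`. Genes with no valid test (all flagged) are
#' excluded and logged.
#'
#' @param records stage-1 association records ([associate()] output).
#' @param genes gene annotation with `gene_id` and `class`.
#' @param q_max significance threshold (default 0.01, i.e. FDR 1%).
#' @return data.frame: `gene_id`, `gene_class`, `n_tests`, `min_p`,
#'   `bonferroni_min_p`, `q_value`, `significant`; attribute
#'   `excluded_genes` lists genes dropped for having zero tests.
#' @export
gene_wise_significance <- function(records, genes, q_max = 0.01) {
  rec <- records[records$stage == 1L, , drop = FALSE]
  rec <- rec[!duplicated(rec[, c("gene_id", "variant_id")]), , drop = FALSE]
  valid <- rec[!is.na(rec$p_value), , drop = FALSE]
  all_genes <- unique(rec$gene_id)
  tested <- unique(valid$gene_id)
  excluded <- setdiff(all_genes, tested)
  if (!length(tested))
    stop("no gene has a valid stage-1 test")
  n_tests <- table(valid$gene_id)[tested]
  min_p <- vapply(tested, function(g)
    min(valid$p_value[valid$gene_id == g]), 0)
  cls <- genes$class[match(tested, genes$gene_id)]
  if (anyNA(cls)) stop("gene class missing for: ",
                       paste(tested[is.na(cls)], collapse = ", "))
  out <- data.frame(gene_id = tested, gene_class = cls,
                    n_tests = as.integer(n_tests),
                    min_p = min_p,
                    bonferroni_min_p = pmin(1, as.integer(n_tests) * min_p),
                    q_value = NA_real_, stringsAsFactors = FALSE)
  for (cl in unique(out$gene_class)) {
    sel <- out$gene_class == cl
    out$q_value[sel] <- bh_qvalues(out$bonferroni_min_p[sel])
  }
  out$significant <- out$q_value <= q_max
  attr(out, "excluded_genes") <- excluded
  rownames(out) <- NULL
  out
}

#' Variant-level FDR for the second stage
#'
#' One pooled Benjamini-Hochberg pass across all stage-2 records of all
#' significant target genes.
#'
#' @param records stage-2 association records.
#' @return the records with a `q_value` column appended (`NA` for
#'   flagged records without a p-value).
#' @export
variant_level_fdr <- function(records) {
  records$q_value <- NA_real_
  ok <- !is.na(records$p_value)
  records$q_value[ok] <- bh_qvalues(records$p_value[ok])
  records
}

#' Peak eQTL variant for a gene
#'
#' The variant with the smallest association p-value across all supplied
#' records (both stages). Ties break deterministically: larger \|t\|,
#' then smaller genomic position.
#'
#' @param gene_id gene to query.
#' @param records combined stage-1 + stage-2 records.
#' @param variant_meta data.frame with `id` and `pos` for the tie-break.
#' @return list: `variant_id`, `p_value`, `t_stat`.
#' @export
find_peak_variant <- function(gene_id, records, variant_meta) {
  rec <- records[records$gene_id == gene_id & !is.na(records$p_value), ,
                 drop = FALSE]
  rec <- rec[!duplicated(rec$variant_id), , drop = FALSE]
  if (!nrow(rec)) stop("gene has no valid association record: ", gene_id)
  pos <- variant_meta$pos[match(rec$variant_id, variant_meta$id)]
  ord <- order(rec$p_value, -abs(rec$t_stat), pos)
  best <- rec[ord[1], ]
  list(variant_id = best$variant_id, p_value = best$p_value,
       t_stat = best$t_stat)
}

#' Classify one (locus, gene) pair into Group 1/2/3
#'
#' The LD anchor is the maximum r-squared between the gene's peak eQTL
#' variant and any of the locus's risk variants. Group 1: r-squared >=
#' `ld_threshold` (boundary inclusive); Group 2: in
#' \[`group2_floor`, `ld_threshold`); Group 3: below `group2_floor`.
#'
#' @param locus one locus from [build_loci()].
#' @param gene_id the classified gene.
#' @param peak_variant_id the gene's peak eQTL variant.
#' @param geno the [genotype_matrix()].
#' @param ld_threshold Group-1 bound (default 0.5).
#' @param group2_floor Group-2 lower bound (default 0.2).
#' @return data.frame row: `locus_id`, `gene_id`, `peak_variant_id`,
#'   `r2_to_risk`, `group`.
#' @export
classify_gene <- function(locus, gene_id, peak_variant_id, geno,
                          ld_threshold = 0.5, group2_floor = 0.2) {
  pk <- match(peak_variant_id, geno$variants$id)
  if (is.na(pk)) stop("peak variant not in genotypes: ", peak_variant_id)
  pkd <- geno$dosages[, pk]
  if (sd(pkd, na.rm = TRUE) == 0)
    stop("monomorphic peak variant: ", peak_variant_id)
  r2 <- max(vapply(locus$risk_variants, function(rv) {
    j <- match(rv, geno$variants$id)
    tryCatch(ld_r2(pkd, geno$dosages[, j]), error = function(e) 0)
  }, 0))
  group <- if (r2 >= ld_threshold) 1L else if (r2 >= group2_floor) 2L else 3L
  data.frame(locus_id = locus$locus_id, gene_id = gene_id,
             peak_variant_id = peak_variant_id, r2_to_risk = r2,
             group = group, stringsAsFactors = FALSE)
}

#' Classify all significant genes against their loci
#'
#' For each gene-wise significant gene: find the peak variant over the
#' combined stage-1 + stage-2 records, then emit one Group call per
#' locus whose stage-1 scan included the gene.
#'
#' @param significances [gene_wise_significance()] output.
#' @param records1,records2 stage-1 and stage-2 association records.
#' @param pairs1 stage-1 pair table (carries the gene-locus incidence).
#' @param loci list from [build_loci()].
#' @param geno the [genotype_matrix()].
#' @param ld_threshold,group2_floor Group bounds.
#' @return data.frame of per-(locus, gene) calls: `locus_id`, `gene_id`,
#'   `gene_class`, `peak_variant_id`, `peak_p`, `r2_to_risk`, `group`.
#' @export
classify_genes <- function(significances, records1, records2, pairs1,
                           loci, geno, ld_threshold = 0.5,
                           group2_floor = 0.2) {
  sig <- significances[significances$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(locus_id = character(), gene_id = character(),
                      gene_class = character(),
                      peak_variant_id = character(), peak_p = numeric(),
                      r2_to_risk = numeric(), group = integer(),
                      stringsAsFactors = FALSE))
  combined <- rbind(records1[, c("gene_id", "variant_id", "t_stat",
                                 "p_value")],
                    records2[, c("gene_id", "variant_id", "t_stat",
                                 "p_value")])
  locus_by_id <- setNames(loci, vapply(loci, `[[`, "", "locus_id"))
  out <- list(); i <- 0L
  for (gi in seq_len(nrow(sig))) {
    gid <- sig$gene_id[gi]
    peak <- find_peak_variant(gid, combined, geno$variants)
    for (lid in unique(pairs1$locus_id[pairs1$gene_id == gid])) {
      call <- classify_gene(locus_by_id[[lid]], gid, peak$variant_id,
                            geno, ld_threshold, group2_floor)
      call$gene_class <- sig$gene_class[gi]
      call$peak_p <- peak$p_value
      i <- i + 1L
      out[[i]] <- call
    }
  }
  res <- do.call(rbind, out)
  res[, c("locus_id", "gene_id", "gene_class", "peak_variant_id",
          "peak_p", "r2_to_risk", "group")]
}

#' Format a percentage the way the study tables print them
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimal places (0 for whole percents, 1 for locus
#'   fractions).
#' @return character percentage without the % sign (e.g. `"52.0"`).
#' @export
report_percent <- function(num, den, digits = 0) {
  sprintf(paste0("%.", digits, "f"), round(100 * num / den, digits))
}

#' Summary tables: gene groups, locus tallies
#'
#' Per-class gene counts by Group, where each unique gene is counted
#' once, in its best (highest-LD, i.e. lowest-numbered) Group across
#' loci; plus locus-level tallies: loci with at least one significant
#' gene and loci with at least one Group-1 gene, with percentages
#' rendered at one decimal for the locus fraction and whole percents
#' elsewhere.
#'
#' @param calls [classify_genes()] output.
#' @param significances [gene_wise_significance()] output.
#' @param loci list from [build_loci()].
#' @return list: `gene_groups` (class x group count table incl. per-class
#'   group percentages), `locus_summary`, `totals`.
#' @export
summarize_calls <- function(calls, significances, loci) {
  classes <- c("protein_coding", "lncRNA", "other")
  groups <- 1:3
  tab <- matrix(0L, length(classes), length(groups),
                dimnames = list(classes, paste0("group", groups)))
  if (nrow(calls)) {
    best <- do.call(rbind, lapply(split(calls, calls$gene_id), function(d)
      d[which.min(d$group), , drop = FALSE]))
    for (cl in classes) for (g in groups)
      tab[cl, paste0("group", g)] <-
        sum(best$gene_class == cl & best$group == g)
  } else best <- calls
  n_loci <- length(loci)
  sig_loci <- unique(calls$locus_id)
  g1_loci <- unique(calls$locus_id[calls$group == 1L])
  gene_groups <- as.data.frame(tab)
  gene_groups$total <- rowSums(tab)
  gene_groups$pct_group1 <- ifelse(
    gene_groups$total > 0,
    report_percent(gene_groups$group1, gene_groups$total, 0), NA)
  list(
    gene_groups = gene_groups,
    locus_summary = data.frame(
      n_loci = n_loci,
      n_loci_with_signal = length(sig_loci),
      pct_loci_with_signal = if (n_loci)
        report_percent(length(sig_loci), n_loci, 1) else NA,
      n_loci_group1 = length(g1_loci),
      pct_signal_loci_group1 = if (length(sig_loci))
        report_percent(length(g1_loci), length(sig_loci), 0) else NA,
      stringsAsFactors = FALSE),
    totals = data.frame(
      n_significant_genes = sum(significances$significant),
      n_unique_genes_called = if (nrow(calls))
        length(unique(calls$gene_id)) else 0L,
      stringsAsFactors = FALSE))
}
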