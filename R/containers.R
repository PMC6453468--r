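#' Construct a genotype matrix object
#'
#' The central genotype container: a sample x variant matrix of alternate
#' allele dosages (0-2, fractional allowed for imputed variants) plus
#' per-variant metadata. Missing calls are `NA`, never 0.
#'
#' @param dosages numeric matrix, samples in rows (rownames = sample IDs),
#'   variants in columns (colnames = variant IDs), values in \[0, 2\] or `NA`.
#' @param variants data.frame with one row per column of `dosages`:
#'   `id`, `chrom`, `pos` (1-based), and optionally `ref`, `alt`,
#'   `is_imputed` (logical), `allelic_r2` (imputation quality in \[0,1\],
#'   `NA` for genotyped variants).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), is.data.frame(variants),
            ncol(dosages) == nrow(variants))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(variants)))
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$id
  stopifnot(identical(colnames(dosages), as.character(variants$id)))
  if (is.null(variants$is_imputed)) variants$is_imputed <- FALSE
  if (is.null(variants$allelic_r2)) variants$allelic_r2 <- NA_real_
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  # positions strictly increasing within chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("variant positions must be strictly increasing within ", ch)
  }
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%d imputed)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$variants$is_imputed)))
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param geno a [genotype_matrix()].
#' @return integer count.
#' @export
n_samples <- function(geno) nrow(geno$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(geno) ncol(geno$dosages)

#' Subset a genotype matrix by variant ID
#' @param geno a [genotype_matrix()].
#' @param ids variant IDs to keep (order preserved from `geno`).
#' @export
subset_variants <- function(geno, ids) {
  keep <- geno$variants$id %in% ids
  genotype_matrix(geno$dosages[, keep, drop = FALSE],
                  geno$variants[keep, , drop = FALSE])
}

#' Construct an expression matrix object
#'
#' Raw gene x sample counts plus gene metadata; the `normalized` slot is
#' `NULL` until [normalize_expression()] fills it.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames =
#'   gene IDs), samples in columns.
#' @param genes data.frame with `gene_id`, `class` (one of
#'   `protein_coding`, `lncRNA`, `other`), `chrom`, `tss`, `tes`, and
#'   optionally `strand` and `gc_fraction`.
#' @param normalized optional normalized matrix of the same shape.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, genes, normalized = NULL) {
  stopifnot(is.matrix(counts), is.data.frame(genes),
            nrow(counts) == nrow(genes))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "class", "chrom", "tss", "tes") %in% names(genes)))
  if (is.null(rownames(counts))) rownames(counts) <- genes$gene_id
  stopifnot(identical(rownames(counts), as.character(genes$gene_id)))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  bad <- genes$tss > genes$tes
  if (any(bad)) stop("tss > tes for gene(s): ",
                     paste(genes$gene_id[bad], collapse = ", "))
  badc <- !genes$class %in% c("protein_coding", "lncRNA", "other")
  if (any(badc)) stop("unknown gene class label: ",
                      paste(unique(genes$class[badc]), collapse = ", "))
  if (is.null(genes$gc_fraction)) genes$gc_fraction <- NA_real_
  if (!is.null(normalized))
    stopifnot(identical(dim(normalized), dim(counts)))
  structure(list(counts = counts, normalized = normalized, genes = genes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) " (raw)" else " (normalized)"))
  invisible(x)
}
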