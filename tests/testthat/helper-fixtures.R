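# handcrafted micro-fixtures built in code

# genotype matrix from a list of dosage vectors (one chromosome,
# positions 1000, 2000, ...)
tiny_geno <- function(dosage_list, is_imputed = NULL, allelic_r2 = NULL,
                      chrom = "chr1") {
  ids <- names(dosage_list)
  m <- do.call(cbind, dosage_list)
  colnames(m) <- ids
  rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  n <- length(ids)
  genotype_matrix(m, data.frame(
    id = ids, chrom = chrom, pos = 1000 * seq_len(n),
    ref = "A", alt = "G",
    is_imputed = is_imputed %||% rep(FALSE, n),
    allelic_r2 = allelic_r2 %||% rep(NA_real_, n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expression matrix from a counts matrix and minimal annotation
tiny_expr <- function(counts, chrom = NULL, class = NULL, tss = NULL,
                      gc = NULL) {
  m <- nrow(counts)
  genes <- data.frame(
    gene_id = rownames(counts),
    class = class %||% rep("protein_coding", m),
    chrom = chrom %||% rep("chr1", m),
    tss = tss %||% (1e5 * seq_len(m)),
    tes = (tss %||% (1e5 * seq_len(m))) + 1e4,
    strand = "+",
    gc_fraction = gc %||% seq(0.35, 0.65, length.out = m),
    stringsAsFactors = FALSE)
  expression_matrix(counts, genes)
}

# correlated dosage pair via haplotype copying: realized r2 ~ tau^2
copy_dosage <- function(causal_h1, causal_h2, tau, f) {
  n <- length(causal_h1)
  c1 <- ifelse(rbinom(n, 1, tau) == 1, causal_h1, rbinom(n, 1, f))
  c2 <- ifelse(rbinom(n, 1, tau) == 1, causal_h2, rbinom(n, 1, f))
  c1 + c2
}

# one full planted-effect study + pipeline run; returns what the
# recovery tests score
run_recovery_rep <- function(seed, beta = 0.6, tags = c("high", "low")) {
  cfg <- sim_config(n_samples = 400L, n_genes = 100L, seed = seed)
  st <- simulate_study(cfg, effects = list(list(beta = beta, tags = tags)))
  inp <- suppressWarnings(
    load_inputs(st$geno, st$expr, st$covariates, st$risk))
  res <- run_pipeline(inp, run_config(max_pcs = 5))
  gid <- st$truth$causal_pairs$gene_id
  tm <- st$truth$tag_map
  locus_of <- function(tag) {
    hit <- vapply(res$loci, function(l) tag %in% l$risk_variants, TRUE)
    if (!any(hit)) return(NA_character_)
    res$loci[[which(hit)[1]]]$locus_id
  }
  group_at <- function(bin) {
    tag <- tm$risk_variant_id[tm$expected_r2_bin == bin]
    if (!length(tag)) return(NA_integer_)
    g <- res$calls$group[res$calls$gene_id == gid &
                           res$calls$locus_id == locus_of(tag[1])]
    if (length(g) == 1) g else NA_integer_
  }
  list(significant = gid %in%
         res$significance$gene_id[res$significance$significant],
       group_high = group_at("high"),
       group_low = group_at("low"),
       result = res, study = st)
}
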