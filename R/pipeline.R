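#' Pipeline run configuration
#'
#' Collects every threshold of the analysis with its study default:
#' variant QC (95% call rate, HWE p 1e-5, 1% MAF, allelic r-squared 0.3),
#' gene filter (median raw count 8), covariates (PCs each explaining >1%
#' variance), risk regions (+/-100 kb), LD locus membership
#' (r-squared 0.5), cis windows (+/-1.1 Mb, both stages), gene-wise FDR
#' (q <= 1%), Group-2 floor (r-squared 0.2), and the variant-level
#' significance shade used in regional tables (q <= 0.05).
#'
#' @param ... overrides of the defaults listed above.
#' @return object of class `eqtl_run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(call_rate_min = 0.95,
              hwe_p_min = 1e-5,
              maf_min = 0.01,
              allelic_r2_min = 0.3,
              median_count_min = 8,
              gc_correct = TRUE,
              pc_var_min = 0.01,
              max_pcs = Inf,
              region_flank = 1e5,
              ld_threshold = 0.5,
              group2_floor = 0.2,
              cis_window = 1.1e6,
              gene_q_max = 0.01,
              variant_q_sig = 0.05,
              seed = 1L,
              outdir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, dots)
  class(cfg) <- "eqtl_run_config"
  cfg
}

#' Serialize / restore a run configuration
#'
#' JSON round-trip used for provenance; [read_config()] restores an
#' object equal to the one written.
#'
#' @param cfg an [run_config()] object.
#' @param path JSON path.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$max_pcs <- if (is.infinite(x$max_pcs)) "Inf" else x$max_pcs
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$max_pcs, "Inf")) x$max_pcs <- Inf
  # JSON does not distinguish integer from double; restore double storage
  x <- lapply(x, function(v) if (is.integer(v)) as.numeric(v) else v)
  if (!is.null(x$seed)) x$seed <- as.integer(x$seed)
  do.call(run_config, x[!vapply(x, is.null, TRUE)])
}

#' Stable hash of a run configuration
#'
#' Hashes the analysis parameters only; `outdir` is a deployment detail
#' and does not enter the hash.
#'
#' @param cfg an [run_config()] object.
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$outdir <- NULL
  rlang::hash(x)
}

#' Validate and reconcile pipeline inputs
#'
#' Intersects sample IDs across genotypes, expression, and covariates
#' (warning on drops; failure below 3 shared samples), checks gene
#' coordinates (`tss <= tes`, positive positions) and class labels, and
#' returns the aligned bundle.
#'
#' @param geno a [genotype_matrix()].
#' @param expr an [expression_matrix()] (raw counts).
#' @param covariates data.frame with `sample_id`, `lymphocyte_pct`,
#'   `epithelial_pct`.
#' @param risk risk-variant data.frame (`rsid`, `chrom`, `pos`).
#' @return list with the sample-aligned `geno`, `expr`, `covariates`,
#'   `risk`, and `log` (character messages).
#' @export
load_inputs <- function(geno, expr, covariates, risk) {
  log <- character()
  shared <- Reduce(intersect, list(rownames(geno$dosages),
                                   colnames(expr$counts),
                                   covariates$sample_id))
  dropped <- setdiff(unique(c(rownames(geno$dosages),
                              colnames(expr$counts),
                              covariates$sample_id)), shared)
  if (length(dropped)) {
    msg <- sprintf("dropped %d sample(s) absent from some input: %s",
                   length(dropped),
                   paste(head(dropped, 5), collapse = ", "))
    warning(msg)
    log <- c(log, msg)
  }
  if (length(shared) < 3) stop("fewer than 3 shared samples across inputs")
  if (any(geno$variants$pos <= 0)) stop("non-positive variant position")
  if (any(expr$genes$tss <= 0)) stop("non-positive gene coordinate")
  geno$dosages <- geno$dosages[shared, , drop = FALSE]
  cts <- expr$counts[, shared, drop = FALSE]
  expr <- expression_matrix(cts, expr$genes)
  covariates <- covariates[match(shared, covariates$sample_id), ,
                           drop = FALSE]
  log <- c(log, sprintf("%d shared samples; %d variants; %d genes",
                        length(shared), n_variants(geno),
                        nrow(expr$counts)))
  list(geno = geno, expr = expr, covariates = covariates, risk = risk,
       log = log)
}

#' Run the full two-stage eQTL pipeline
#'
#' Executes, in order: variant QC -> missing-dosage imputation -> gene
#' filter -> normalization -> covariate assembly (cell fractions +
#' expression PCs) -> risk-variant screening -> regions -> loci ->
#' stage-1 scan -> gene-centric significance -> stage-2 scan ->
#' variant-level FDR -> peak finding and Group classification ->
#' summary. Each stage appends its in/out bookkeeping to the run log.
#' When `cfg$outdir` is set, every table is persisted as a
#' provenance-headed TSV plus a JSON summary.
#'
#' @param inputs a [load_inputs()] bundle (or any list with aligned
#'   `geno`, `expr`, `covariates`, `risk`).
#' @param cfg an [run_config()].
#' @return object of class `eqtl_run_result`: list with `locus_table`,
#'   `loci`, `records1`, `records2`, `significance`, `calls`, `summary`,
#'   `exclusions`, `risk_screen`, `covariate_names`, `log`, `provenance`.
#' @export
run_pipeline <- function(inputs, cfg = run_config()) {
  stopifnot(inherits(cfg, "eqtl_run_config"))
  log <- c(inputs$log %||% character())
  note <- function(...) log <<- c(log, sprintf(...))

  # --- variant QC ---------------------------------------------------
  vq <- filter_variants(inputs$geno, cfg$call_rate_min, cfg$hwe_p_min,
                        cfg$maf_min, cfg$allelic_r2_min)
  geno <- impute_missing_dosages(vq$geno)
  note("variant QC: %d in -> %d out (%d excluded)",
       n_variants(inputs$geno), n_variants(geno), nrow(vq$exclusions))

  # --- gene filter + normalization ---------------------------------
  expr <- filter_genes(inputs$expr, cfg$median_count_min)
  note("gene filter: %d in -> %d out", nrow(inputs$expr$counts),
       nrow(expr$counts))
  expr <- normalize_expression(expr, gc_correct = cfg$gc_correct)

  # --- covariates ---------------------------------------------------
  pcs <- compute_expression_pcs(expr, cfg$pc_var_min, cfg$max_pcs)
  X <- assemble_covariates(inputs$covariates, pcs,
                           colnames(expr$normalized))
  note("covariates: 2 cell fractions + %d expression PCs (cum. %.1f%% var)",
       ncol(pcs$scores), 100 * pcs$cumulative)

  # --- risk loci ----------------------------------------------------
  screen <- screen_risk_variants(inputs$risk, geno, cfg$maf_min)
  note("risk variants: %d listed -> %d included (%d excluded)",
       nrow(screen), sum(screen$status == "included"),
       sum(screen$status == "excluded"))
  regions <- build_regions(screen, cfg$region_flank)
  loci <- build_loci(regions, geno, cfg$ld_threshold)
  loci <- annotate_locus_positions(loci, geno)
  note("loci: %d regions -> %d loci, %d LD variants total",
       nrow(regions), length(loci),
       length(unique(unlist(lapply(loci, `[[`, "ld_variants")))))

  # --- residualization ---------------------------------------------
  expr_res <- residualize(expr$normalized, X)
  geno_res <- residualize(t(geno$dosages), X)

  # --- stage 1 ------------------------------------------------------
  pairs1 <- stage1_pairs(loci, expr$genes, cfg$cis_window)
  if (!nrow(pairs1)) stop("stage 1: no eligible gene-variant pairs")
  records1 <- associate(expr_res, geno_res, pairs1, ncol(X))
  note("stage 1: %d tests over %d variants x %d genes",
       length(unique(paste(records1$gene_id, records1$variant_id))),
       length(unique(records1$variant_id)),
       length(unique(records1$gene_id)))
  signif <- gene_wise_significance(records1, expr$genes, cfg$gene_q_max)
  note("gene-wise significance: %d of %d genes at q <= %g",
       sum(signif$significant), nrow(signif), cfg$gene_q_max)

  # --- stage 2 ------------------------------------------------------
  targets <- expr$genes[expr$genes$gene_id %in%
                          signif$gene_id[signif$significant], ,
                        drop = FALSE]
  if (nrow(targets)) {
    pairs2 <- stage2_pairs(targets, geno, cfg$cis_window)
    records2 <- associate(expr_res, geno_res, pairs2, ncol(X))
    records2 <- variant_level_fdr(records2)
    note("stage 2: %d tests over %d target genes",
         nrow(records2), nrow(targets))
  } else {
    records2 <- cbind(records1[0, ], q_value = numeric(0))
    note("stage 2: skipped (no significant genes)")
  }

  # --- classification ----------------------------------------------
  calls <- classify_genes(signif, records1, records2, pairs1, loci, geno,
                          cfg$ld_threshold, cfg$group2_floor)
  summary <- summarize_calls(calls, signif, loci)
  note("classification: %d (locus, gene) calls; %d unique genes",
       nrow(calls), summary$totals$n_unique_genes_called)

  result <- structure(list(
    locus_table = locus_table(loci),
    loci = loci,
    records1 = records1,
    records2 = records2,
    significance = signif,
    calls = calls,
    summary = summary,
    exclusions = vq$exclusions,
    risk_screen = screen,
    covariate_names = colnames(X),
    log = log,
    provenance = list(config_hash = config_hash(cfg),
                      package_version =
                        as.character(utils::packageVersion("riskeqtl")),
                      seed = cfg$seed)),
    class = "eqtl_run_result")
  if (!is.null(cfg$outdir)) write_run_result(result, cfg)
  result
}

#' @export
print.eqtl_run_result <- function(x, ...) {
  cat("<eqtl_run_result>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Persist every pipeline table
#'
#' @param result an `eqtl_run_result`.
#' @param cfg the [run_config()] used (supplies `outdir` and provenance).
#' @export
write_run_result <- function(result, cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(config_hash = result$provenance$config_hash,
               package = paste0("riskeqtl ",
                                result$provenance$package_version),
               seed = result$provenance$seed)
  p <- function(f) file.path(cfg$outdir, f)
  write_tsv_table(result$locus_table, p("loci.tsv"), prov)
  write_tsv_table(result$records1, p("stage1_associations.tsv"), prov)
  write_tsv_table(result$records2, p("stage2_associations.tsv"), prov)
  write_tsv_table(result$significance, p("gene_significance.tsv"), prov)
  write_tsv_table(result$calls, p("gene_group_calls.tsv"), prov)
  write_tsv_table(result$exclusions, p("variant_exclusions.tsv"), prov)
  write_tsv_table(result$risk_screen, p("risk_variant_screen.tsv"), prov)
  jsonlite::write_json(
    list(gene_groups = result$summary$gene_groups,
         locus_summary = result$summary$locus_summary,
         totals = result$summary$totals,
         provenance = result$provenance),
    p("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$log, p("run_log.txt"))
  invisible(cfg$outdir)
}

#' Regional association table for one gene
#'
#' Per stage-2 variant of the gene: position, -log10 p, LD r-squared to
#' the locus's risk variant(s), a significance flag (variant-level
#' q <= `cfg$variant_q_sig`), and a marker for the risk variant rows —
#' the substrate of a regional association plot.
#'
#' @param result an `eqtl_run_result`.
#' @param gene_id gene present in the stage-2 results.
#' @param geno the QC'd [genotype_matrix()] (for LD and positions).
#' @param cfg the [run_config()] used.
#' @return data.frame: `variant_id`, `pos`, `neg_log10_p`, `r2_to_risk`,
#'   `significant`, `is_risk_variant`.
#' @export
emit_regional_table <- function(result, gene_id, geno,
                                cfg = run_config()) {
  rec <- result$records2[result$records2$gene_id == gene_id &
                           !is.na(result$records2$p_value), , drop = FALSE]
  if (!nrow(rec)) stop("gene not in stage-2 results: ", gene_id)
  call <- result$calls[result$calls$gene_id == gene_id, , drop = FALSE]
  # LD shading anchors on the gene's highest-LD (best-group) locus call
  if (nrow(call) > 1)
    call <- call[order(call$group, -call$r2_to_risk), , drop = FALSE]
  risk_ids <- if (nrow(call)) {
    loc <- result$loci[[match(call$locus_id[1],
                              vapply(result$loci, `[[`, "", "locus_id"))]]
    loc$risk_variants
  } else character()
  idx <- match(rec$variant_id, geno$variants$id)
  r2 <- rep(NA_real_, nrow(rec))
  if (length(risk_ids)) {
    for (rv in risk_ids) {
      j <- match(rv, geno$variants$id)
      vals <- vapply(idx, function(i)
        tryCatch(ld_r2(geno$dosages[, i], geno$dosages[, j]),
                 error = function(e) NA_real_), 0)
      r2 <- pmax(r2, vals, na.rm = TRUE)
    }
  }
  data.frame(variant_id = rec$variant_id,
             pos = geno$variants$pos[idx],
             neg_log10_p = -log10(rec$p_value),
             r2_to_risk = r2,
             significant = !is.na(rec$q_value) &
               rec$q_value <= cfg$variant_q_sig,
             is_risk_variant = rec$variant_id %in% risk_ids,
             stringsAsFactors = FALSE)
}
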