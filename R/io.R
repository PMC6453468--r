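#' Write a table as TSV with provenance header lines
#'
#' Tab-delimited, UTF-8, with `#`-prefixed provenance comment lines
#' (key: value) before the column header, so every stage output is
#' self-describing and re-ingestable with [read_tsv_table()].
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param provenance named list rendered as `# key: value` lines.
#' @export
write_tsv_table <- function(df, path, provenance = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(x)
      if (is.numeric(x)) format(x, digits = 15, trim = TRUE,
                                scientific = FALSE) else as.character(x))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_tsv_table
#' @return `read_tsv_table`: the data.frame (provenance lines attached as
#'   attribute `provenance`).
#' @export
read_tsv_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  prov <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- data.table::fread(text = paste(body, collapse = "\n"),
                          sep = "\t", data.table = FALSE)
  attr(df, "provenance") <- prov
  df
}

#' Read genotypes from a dosage TSV
#'
#' Expects a sample x variant table: first column `sample_id`, remaining
#' columns one per variant, plus a companion variant metadata TSV
#' (`id`, `chrom`, `pos`, optionally `ref`, `alt`, `is_imputed`,
#' `allelic_r2`). Missing dosages may be encoded as `NA`.
#'
#' @param dosage_path dosage TSV path.
#' @param variant_path variant metadata TSV path.
#' @return a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(dosage_path, variant_path) {
  d <- data.table::fread(dosage_path, sep = "\t", data.table = FALSE)
  v <- data.table::fread(variant_path, sep = "\t", data.table = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  v <- v[match(colnames(m), v$id), , drop = FALSE]
  genotype_matrix(m, v)
}

#' Read genotypes from a VCF
#'
#' Uses the `DS` (dosage) FORMAT field when present, else converts `GT`
#' hard calls to alternate-allele counts. Requires the `vcfR` package.
#'
#' @param path VCF path (v4.x, plain text or gzipped).
#' @return a [genotype_matrix()]; an attribute `dosage_source` records
#'   whether `DS` or `GT` was used.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  fmt <- unique(fix$FORMAT %||% NULL)
  has_ds <- any(grepl("DS", vcf@gt[, 1]))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    src <- "DS"
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(col, function(g) {
        if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
        sum(as.integer(strsplit(gsub("\\|", "/", g), "/")[[1]]))
      }, 0)
    })
    src <- "GT"
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  rownames(ds) <- ids
  v <- data.frame(id = ids, chrom = fix$CHROM, pos = as.numeric(fix$POS),
                  ref = fix$REF, alt = fix$ALT,
                  is_imputed = grepl("IMPUTED", fix$INFO %||% ""),
                  allelic_r2 = NA_real_, stringsAsFactors = FALSE)
  g <- genotype_matrix(t(ds), v)
  attr(g, "dosage_source") <- src
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a minimal VCF for a genotype matrix
#'
#' Emits VCF v4.2 with `GT` (dosage rounded to hard calls) and `DS`
#' (the dosage itself) FORMAT fields.
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       rownames(geno$dosages)), collapse = "\t")), con)
  v <- geno$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(n_variants(geno))) {
    d <- geno$dosages[, j]
    hard <- pmin(pmax(round(d), 0), 2)
    cells <- ifelse(is.na(d), "./.:.",
                    paste0(gt_codes[hard + 1], ":",
                           format(d, trim = TRUE, digits = 4)))
    writeLines(paste(c(v$chrom[j], format(v$pos[j], scientific = FALSE),
                       v$id[j], v$ref[j] %||% "A", v$alt[j] %||% "G",
                       ".", "PASS", ".", "GT:DS", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a synthetic study bundle to disk
#'
#' Emits the full plain-text fixture set: dosage + variant TSVs, a
#' minimal VCF, gene x sample counts TSV, gene annotation TSV,
#' risk-variant TSV, covariate TSV, and the ground-truth JSON.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  dos <- data.frame(sample_id = rownames(study$geno$dosages),
                    study$geno$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv_table(dos, p("dosages.tsv"))
  write_tsv_table(study$geno$variants, p("variants.tsv"))
  write_vcf(study$geno, p("genotypes.vcf"))
  cts <- data.frame(gene_id = rownames(study$expr$counts),
                    study$expr$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv_table(cts, p("counts.tsv"))
  write_tsv_table(study$genes, p("genes.tsv"))
  write_tsv_table(study$covariates, p("covariates.tsv"))
  if (!is.null(study$risk))
    write_tsv_table(study$risk, p("risk_variants.tsv"))
  if (!is.null(study$truth))
    jsonlite::write_json(unclass(study$truth), p("truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study bundle written by [write_study_bundle()]
#'
#' @param dir bundle directory.
#' @return list with `geno`, `expr`, `genes`, `covariates`, `risk`
#'   (NULL when absent), `truth` (NULL when absent).
#' @export
read_study_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  geno <- read_dosage_tsv(p("dosages.tsv"), p("variants.tsv"))
  genes <- read_tsv_table(p("genes.tsv"))
  cts <- read_tsv_table(p("counts.tsv"))
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts[[1]]
  expr <- expression_matrix(m, genes)
  covariates <- read_tsv_table(p("covariates.tsv"))
  risk <- if (file.exists(p("risk_variants.tsv")))
    read_tsv_table(p("risk_variants.tsv")) else NULL
  truth <- if (file.exists(p("truth.json")))
    jsonlite::read_json(p("truth.json"), simplifyVector = TRUE) else NULL
  list(geno = geno, expr = expr, genes = genes, covariates = covariates,
       risk = risk, truth = truth)
}

#' Read gene counts from a MatrixMarket sparse file
#'
#' @param mtx_path MTX file; `gene_path`/`sample_path` one-column files
#'   of row and column names.
#' @return dense counts matrix (genes x samples).
#' @export
read_counts_mtx <- function(mtx_path, gene_path, sample_path) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("reading MTX requires the Matrix package")
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(gene_path)
  colnames(m) <- readLines(sample_path)
  storage.mode(m) <- "double"
  m
}
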