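#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the simulated study: cohort size, LD-block
#' genotype structure, gene panel, and the count model. Defaults emulate
#' the shape of a normal prostate tissue eQTL cohort: 471 samples,
#' moderately strong LD blocks, negative-binomial RNA-seq counts with GC
#' and sequencing-depth bias, and lymphocyte/epithelial cell-fraction
#' covariates.
#'
#' Genotypes are produced by founder-haplotype copying: each LD block has
#' `founder_haplotypes_per_block` founder haplotypes, and every sample
#' draws two founders per block independently. Fewer founders mean
#' stronger within-block LD; cross-block draws are independent so
#' cross-block r-squared is near zero.
#'
#' All randomness flows from `seed`; generator stages draw from fixed
#' per-stage offsets of it (genotypes, gene annotation, truth selection,
#' expression, risk list) so fixtures are byte-stable across calls.
#'
#' @param n_samples number of samples.
#' @param n_blocks number of LD blocks.
#' @param snps_per_block variants per block.
#' @param founder_haplotypes_per_block founder pool size per block
#'   (controls LD strength; 2 forces within-block r-squared = 1).
#' @param block_span_bp physical span of one block, bp.
#' @param n_genes number of genes on the panel.
#' @param genome_span_bp total simulated span (one chromosome), bp.
#' @param maf_floor minimum empirical minor allele frequency per variant;
#'   monomorphic or too-rare draws are rejection-resampled.
#' @param effect_sizes default standardized per-allele effect sizes
#'   (units of residual s.d. of log2 expression) used by [make_truth()].
#' @param dispersion negative-binomial overdispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param depth_lognormal_sigma s.d. of log-normal library-depth factors;
#'   0 gives equal depths.
#' @param gc_bias_amplitude slope of the planted linear GC effect on
#'   log2 mean expression (log2 units across the full GC range is about
#'   1.2 * amplitude); 0 disables GC bias.
#' @param baseline_log2_range range of per-gene baseline log2 mean counts.
#' @param cell_fraction_effects named vector: log2-expression shift per
#'   percentage point of lymphocyte and epithelial fraction.
#' @param gene_class_props proportions of protein_coding / lncRNA / other
#'   genes on the panel.
#' @param seed integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 471L,
                       n_blocks = 12L,
                       snps_per_block = 10L,
                       founder_haplotypes_per_block = 6L,
                       block_span_bp = 60000L,
                       n_genes = 150L,
                       genome_span_bp = 12e6,
                       maf_floor = 0.05,
                       effect_sizes = c(0.6),
                       dispersion = 0.02,
                       depth_lognormal_sigma = 0.25,
                       gc_bias_amplitude = 1.0,
                       baseline_log2_range = c(4, 10),
                       cell_fraction_effects = c(lymphocyte = 0.03,
                                                 epithelial = 0.015),
                       gene_class_props = c(protein_coding = 0.65,
                                            lncRNA = 0.08,
                                            other = 0.27),
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_blocks = as.integer(n_blocks),
              snps_per_block = as.integer(snps_per_block),
              founder_haplotypes_per_block =
                as.integer(founder_haplotypes_per_block),
              block_span_bp = as.numeric(block_span_bp),
              n_genes = as.integer(n_genes),
              genome_span_bp = as.numeric(genome_span_bp),
              maf_floor = maf_floor,
              effect_sizes = effect_sizes,
              dispersion = dispersion,
              depth_lognormal_sigma = depth_lognormal_sigma,
              gc_bias_amplitude = gc_bias_amplitude,
              baseline_log2_range = baseline_log2_range,
              cell_fraction_effects = cell_fraction_effects,
              gene_class_props = gene_class_props,
              seed = as.integer(seed))
  counts <- c("n_samples", "n_blocks", "snps_per_block",
              "founder_haplotypes_per_block", "n_genes")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop(nm, " must be >= 1")
  if (cfg$maf_floor <= 0 || cfg$maf_floor >= 0.5)
    stop("maf_floor must lie in (0, 0.5)")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$depth_lognormal_sigma < 0)
    stop("depth_lognormal_sigma must be >= 0")
  if (cfg$n_blocks * cfg$block_span_bp > cfg$genome_span_bp)
    stop("blocks do not fit into genome_span_bp")
  class(cfg) <- "sim_config"
  cfg
}

# fixed per-stage seed offsets; keeps the order of draws stable even when
# stages are regenerated independently
.stage_seed <- function(cfg, stage) {
  off <- c(genotypes = 0L, annotation = 1L, truth = 2L,
           expression = 3L, risk = 4L)
  cfg$seed + off[[stage]]
}

#' Simulate block-LD genotype dosages
#'
#' Founder-haplotype copying per block: founder haplotypes are binary
#' vectors over the block's SNPs; each sample receives two independent
#' founder draws per block and its dosage is the sum of the two founder
#' alleles. Genotypes are therefore hard calls in \{0,1,2\}, in
#' Hardy-Weinberg proportions by construction, with elevated within-block
#' and near-zero cross-block LD. Variants whose empirical MAF falls below
#' `cfg$maf_floor` have their founder allele pattern resampled (bounded
#' retries; an infeasible configuration fails loudly).
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()] with variant IDs `snp_<block>_<index>`,
#'   all on `chr1`, positions sorted within evenly spaced block spans.
#' @export
generate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.stage_seed(cfg, "genotypes"))
  n <- cfg$n_samples
  k <- cfg$founder_haplotypes_per_block
  s <- cfg$snps_per_block
  nb <- cfg$n_blocks
  # feasibility: with k founders the coarsest nonzero founder frequency is
  # 1/k; binomial sampling noise can still reach maf_floor, but a floor
  # above what any founder pattern can deliver is hopeless
  if (1 / k < cfg$maf_floor / 4 && k == 1L)
    stop("founder pool cannot satisfy maf_floor")
  block_starts <- round(seq(1, cfg$genome_span_bp - cfg$block_span_bp,
                            length.out = nb))
  dos <- matrix(NA_real_, n, nb * s)
  ids <- character(nb * s)
  pos <- numeric(nb * s)
  for (b in seq_len(nb)) {
    hap1 <- sample.int(k, n, replace = TRUE)
    hap2 <- sample.int(k, n, replace = TRUE)
    cols <- (b - 1L) * s + seq_len(s)
    for (j in seq_len(s)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        f <- runif(1, 0.2, 0.8)
        pattern <- rbinom(k, 1L, f)
        d <- pattern[hap1] + pattern[hap2]
        maf <- min(mean(d) / 2, 1 - mean(d) / 2)
        if (maf >= cfg$maf_floor) { ok <- TRUE; break }
      }
      if (!ok)
        stop("infeasible sim_config: could not reach maf_floor = ",
             cfg$maf_floor, " with ", k, " founder haplotypes (block ",
             b, ", snp ", j, ")")
      dos[, cols[j]] <- d
    }
    ids[cols] <- sprintf("snp_%02d_%02d", b, seq_len(s))
    pos[cols] <- sort(sample.int(cfg$block_span_bp, s)) + block_starts[b]
  }
  colnames(dos) <- ids
  rownames(dos) <- sprintf("sample_%03d", seq_len(n))
  variants <- data.frame(id = ids, chrom = "chr1", pos = pos,
                         ref = "A", alt = "G",
                         block = rep(seq_len(nb), each = s),
                         is_imputed = FALSE, allelic_r2 = NA_real_,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants)
}

#' Simulate a gene annotation panel
#'
#' Genes are placed uniformly over the simulated span with widths of
#' 5-50 kb, GC fractions in \[0.35, 0.65\], and classes drawn with the
#' configured proportions.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `gene_id`, `class`, `chrom`, `tss`, `tes`,
#'   `strand`, `gc_fraction`, sorted by `tss`.
#' @export
make_gene_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.stage_seed(cfg, "annotation"))
  m <- cfg$n_genes
  tss <- sort(round(runif(m, 1, cfg$genome_span_bp - 50000)))
  width <- round(runif(m, 5000, 50000))
  cls <- sample(names(cfg$gene_class_props), m, replace = TRUE,
                prob = cfg$gene_class_props)
  data.frame(gene_id = sprintf("gene_%04d", seq_len(m)),
             class = cls, chrom = "chr1",
             tss = tss, tes = tss + width,
             strand = sample(c("+", "-"), m, replace = TRUE),
             gc_fraction = runif(m, 0.35, 0.65),
             stringsAsFactors = FALSE)
}

#' Select planted effects and their tag variants
#'
#' Builds the ground-truth table the downstream tests score against. Each
#' requested effect picks one gene and one causal variant within +/-1.1 Mb
#' of the gene span (empirical MAF >= `causal_maf_min`), then one tag
#' variant per requested LD bin to stand in as the "published" risk
#' variant:
#'
#' * `"self"` — the causal variant itself (r-squared 1);
#' * `"high"` — a same-block variant with realized r-squared closest to
#'   `target_r2` (and >= 0.5);
#' * `"low"`  — a variant from a different block, still within
#'   +/-1.1 Mb of the gene, with r-squared < 0.2 to the causal variant.
#'
#' A single causal variant may carry several tags (e.g. one `"high"` and
#' one `"low"`), emulating a gene close to two distinct risk loci.
#'
#' @param geno a [genotype_matrix()] from [generate_genotypes()].
#' @param genes annotation from [make_gene_annotation()].
#' @param cfg the [sim_config()].
#' @param effects list of `list(beta = , tags = )` entries; `beta` is the
#'   standardized per-allele effect, `tags` a character vector over
#'   \{"self","high","low"\}. Defaults to one `"high"`-tagged effect per
#'   entry of `cfg$effect_sizes`.
#' @param causal_maf_min minimum MAF for causal variants.
#' @param target_r2 LD target for `"high"` tags.
#' @param cis_window window used for the causal-within-window invariant.
#' @return An object of class `synthetic_truth`: list with `causal_pairs`
#'   (gene_id, variant_id, beta), `tag_map` (risk_variant_id,
#'   causal_variant_id, expected_r2_bin), and `null_genes`.
#' @export
make_truth <- function(geno, genes, cfg,
                       effects = lapply(cfg$effect_sizes, function(b)
                         list(beta = b, tags = "high")),
                       causal_maf_min = 0.2,
                       target_r2 = 0.8,
                       cis_window = 1.1e6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  set.seed(.stage_seed(cfg, "truth"))
  v <- geno$variants
  maf <- apply(geno$dosages, 2, function(d) {
    p <- mean(d, na.rm = TRUE) / 2; min(p, 1 - p)
  })
  causal_pairs <- data.frame(gene_id = character(), variant_id = character(),
                             beta = numeric(), stringsAsFactors = FALSE)
  tag_map <- data.frame(risk_variant_id = character(),
                        causal_variant_id = character(),
                        expected_r2_bin = character(),
                        stringsAsFactors = FALSE)
  used_genes <- character()
  for (eff in effects) {
    placed <- FALSE
    for (gi in sample(nrow(genes))) {
      g <- genes[gi, ]
      if (g$gene_id %in% used_genes) next
      win <- v$chrom == g$chrom & v$pos >= g$tss - cis_window &
        v$pos <= g$tes + cis_window
      cand <- which(win & maf >= causal_maf_min)
      if (!length(cand)) next
      for (ci in sample(cand, min(length(cand), 20L))) {
        cd <- geno$dosages[, ci]
        tags_found <- list()
        ok <- TRUE
        for (bin in eff$tags) {
          tid <- switch(bin,
            self = v$id[ci],
            high = {
              mates <- which(v$block == v$block[ci] &
                               seq_len(nrow(v)) != ci)
              if (!length(mates)) NA_character_ else {
                r2 <- vapply(mates, function(m)
                  suppressWarnings(cor(cd, geno$dosages[, m]))^2, 0)
                r2[is.na(r2)] <- -1
                in_window <- r2 >= 0.6 & r2 <= 0.95
                if (any(in_window)) {
                  w <- which(in_window)
                  v$id[mates[w[which.min(abs(r2[w] - target_r2))]]]
                } else if (max(r2) >= 0.5) {
                  v$id[mates[which.max(r2)]]
                } else NA_character_
              }
            },
            low = {
              far <- which(win & v$block != v$block[ci])
              if (!length(far)) NA_character_ else {
                r2 <- vapply(far, function(m)
                  suppressWarnings(cor(cd, geno$dosages[, m]))^2, 0)
                r2[is.na(r2)] <- 1
                if (min(r2) >= 0.2) NA_character_ else
                  v$id[far[which.min(r2)]]
              }
            },
            stop("unknown tag bin: ", bin))
          if (is.na(tid)) { ok <- FALSE; break }
          tags_found[[bin]] <- tid
        }
        if (!ok) next
        causal_pairs <- rbind(causal_pairs, data.frame(
          gene_id = g$gene_id, variant_id = v$id[ci], beta = eff$beta,
          stringsAsFactors = FALSE))
        for (bin in names(tags_found))
          tag_map <- rbind(tag_map, data.frame(
            risk_variant_id = tags_found[[bin]],
            causal_variant_id = v$id[ci],
            expected_r2_bin = bin, stringsAsFactors = FALSE))
        used_genes <- c(used_genes, g$gene_id)
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed)
      stop("could not place a planted effect with tags ",
           paste(eff$tags, collapse = "+"),
           "; enlarge the genome or relax causal_maf_min")
  }
  structure(list(causal_pairs = causal_pairs, tag_map = tag_map,
                 null_genes = setdiff(genes$gene_id, used_genes)),
            class = "synthetic_truth")
}

#' Simulate RNA-seq counts and cell-fraction covariates
#'
#' Counts are negative binomial with log2 mean
#' `baseline + beta_log2 * dosage + g_l * lymphocyte + g_e * epithelial +
#' GC term + log2(depth factor)`. Planted standardized effects `beta`
#' (units of residual s.d.) are converted to the log2 scale via the
#' delta-method residual s.d. `sqrt(1/mu + phi) / ln 2` at the gene's
#' baseline mean. The GC term is linear in GC fraction (centered at 0.5)
#' and library-depth factors are log-normal, so the data carry exactly
#' the two biases the normalization stage is built to remove.
#'
#' @param geno a [genotype_matrix()] holding every causal variant.
#' @param genes gene annotation (see [make_gene_annotation()]).
#' @param cfg the [sim_config()].
#' @param truth optional [make_truth()] result; `NULL` plants nothing.
#' @return list with `expr` (an [expression_matrix()]) and `covariates`
#'   (data.frame: sample_id, lymphocyte_pct, epithelial_pct).
#' @export
generate_expression <- function(geno, genes, cfg, truth = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  set.seed(.stage_seed(cfg, "expression"))
  n <- n_samples(geno)
  m <- nrow(genes)
  if (!is.null(truth)) {
    missing <- setdiff(truth$causal_pairs$variant_id, geno$variants$id)
    if (length(missing))
      stop("causal variant(s) absent from genotypes: ",
           paste(missing, collapse = ", "))
  }
  lymph <- runif(n, 0, 2)          # lymphocytes <= 2% by case selection
  epith <- runif(n, 40, 90)        # epithelial content >= 40%
  depth_log2 <- if (cfg$depth_lognormal_sigma > 0)
    rnorm(n, 0, cfg$depth_lognormal_sigma) / log(2) else rep(0, n)
  baseline <- runif(m, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])
  gc_term <- cfg$gc_bias_amplitude * 4 * (genes$gc_fraction - 0.5)
  ce <- cfg$cell_fraction_effects
  sample_term <- ce[["lymphocyte"]] * lymph + ce[["epithelial"]] * epith +
    depth_log2
  log2mu <- outer(baseline + gc_term, sample_term, "+")
  if (!is.null(truth) && nrow(truth$causal_pairs)) {
    for (i in seq_len(nrow(truth$causal_pairs))) {
      cp <- truth$causal_pairs[i, ]
      gi <- match(cp$gene_id, genes$gene_id)
      mu0 <- 2^(baseline[gi] + gc_term[gi])
      sd_resid <- sqrt(1 / mu0 + cfg$dispersion) / log(2)
      log2mu[gi, ] <- log2mu[gi, ] +
        cp$beta * sd_resid * geno$dosages[, cp$variant_id]
    }
  }
  mu <- 2^log2mu
  counts <- if (cfg$dispersion > 0)
    matrix(rnbinom(m * n, mu = mu, size = 1 / cfg$dispersion), m, n)
  else matrix(rpois(m * n, lambda = mu), m, n)
  rownames(counts) <- genes$gene_id
  colnames(counts) <- rownames(geno$dosages)
  list(expr = expression_matrix(counts, genes),
       covariates = data.frame(sample_id = rownames(geno$dosages),
                               lymphocyte_pct = lymph,
                               epithelial_pct = epith,
                               stringsAsFactors = FALSE))
}

#' Emit the "published" risk-variant list for a synthetic truth
#'
#' Risk variants are the tag variants of `truth$tag_map` (not the causal
#' variants themselves). Optional decoys exercise the intake exclusion
#' rules: an entry absent from the genotypes, and, when the data contain
#' one, a variant in perfect LD with a listed tag.
#'
#' @param truth a [make_truth()] result with a non-empty tag map.
#' @param geno the [genotype_matrix()].
#' @param include_absent add a variant not present in the genotype file.
#' @param include_perfect_ld add (if one exists) a same-block variant with
#'   r-squared 1 to a listed tag.
#' @return data.frame: `rsid`, `chrom`, `pos`, `source`.
#' @export
generate_risk_variants <- function(truth, geno, include_absent = TRUE,
                                   include_perfect_ld = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!nrow(truth$tag_map)) stop("tag_map is empty")
  v <- geno$variants
  tag_ids <- unique(truth$tag_map$risk_variant_id)
  idx <- match(tag_ids, v$id)
  out <- data.frame(rsid = tag_ids, chrom = v$chrom[idx], pos = v$pos[idx],
                    source = "synthetic_tag", stringsAsFactors = FALSE)
  if (include_perfect_ld) {
    for (tid in tag_ids) {
      ti <- match(tid, v$id)
      mates <- which(v$block == v$block[ti] & v$id != tid &
                       !v$id %in% out$rsid)
      if (!length(mates)) next
      r2 <- vapply(mates, function(m)
        suppressWarnings(cor(geno$dosages[, ti], geno$dosages[, m]))^2, 0)
      hit <- mates[!is.na(r2) & r2 > 1 - 1e-9]
      if (length(hit)) {
        h <- hit[1]
        out <- rbind(out, data.frame(rsid = v$id[h], chrom = v$chrom[h],
                                     pos = v$pos[h],
                                     source = "synthetic_perfect_ld_decoy",
                                     stringsAsFactors = FALSE))
        break
      }
    }
  }
  if (include_absent)
    out <- rbind(out, data.frame(rsid = "rs_absent_decoy", chrom = "chr1",
                                 pos = max(v$pos) + 54321,
                                 source = "synthetic_absent_decoy",
                                 stringsAsFactors = FALSE))
  out
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper running the generator stages in their fixed order.
#'
#' @param cfg a [sim_config()].
#' @param effects passed to [make_truth()]; `NULL` plants nothing (a null
#'   cohort).
#' @param ... further arguments to [make_truth()].
#' @return list: `geno`, `genes`, `truth` (or NULL), `expr`, `covariates`,
#'   `risk` (or NULL when nothing is planted), `cfg`.
#' @export
simulate_study <- function(cfg, effects = NULL, ...) {
  geno <- generate_genotypes(cfg)
  genes <- make_gene_annotation(cfg)
  truth <- if (is.null(effects)) NULL else
    make_truth(geno, genes, cfg, effects = effects, ...)
  ex <- generate_expression(geno, genes, cfg, truth)
  risk <- if (is.null(truth) || !nrow(truth$tag_map)) NULL else
    generate_risk_variants(truth, geno)
  list(geno = geno, genes = genes, truth = truth, expr = ex$expr,
       covariates = ex$covariates, risk = risk, cfg = cfg)
}
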