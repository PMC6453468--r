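#' Linkage disequilibrium r-squared between two dosage vectors
#'
#' Squared Pearson correlation of allele dosages (genotypic r-squared,
#' the PLINK convention), invariant to allele flips (`d -> 2 - d`).
#' Pairs with missing values are dropped.
#'
#' @param dosage_a,dosage_b numeric dosage vectors of equal length >= 3.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (length(a) < 3) stop("need at least 3 complete observations")
  if (sd(a) == 0 || sd(b) == 0)
    stop("monomorphic input: r-squared undefined")
  min(cor(a, b)^2, 1)
}

# r2 of one variant (by column index) against many, NA where undefined
.ld_r2_vec <- function(dosages, i, js) {
  x <- dosages[, i]
  r <- suppressWarnings(cor(x, dosages[, js, drop = FALSE],
                            use = "pairwise.complete.obs"))
  as.vector(r)^2
}

#' Screen a published risk-variant list against the genotypes
#'
#' Each listed variant is marked `included` or `excluded` with a single
#' reason, checked in order: `not_in_genotypes` (absent from the QC'd
#' genotype file), `low_maf` (MAF below `maf_min`), `perfect_ld`
#' (r-squared 1 with an earlier-listed included risk variant; the
#' first-listed member of such a pair is kept).
#'
#' @param risk_list data.frame with `rsid`, `chrom`, `pos`.
#' @param geno the QC'd [genotype_matrix()].
#' @param maf_min minimum MAF (default 1%).
#' @return the risk list with `status` (`included` / `excluded`) and
#'   `reason` (`NA` when included) columns appended.
#' @export
screen_risk_variants <- function(risk_list, geno, maf_min = 0.01) {
  stopifnot(nrow(risk_list) > 0)
  rl <- as.data.frame(risk_list, stringsAsFactors = FALSE)
  rl$status <- "included"
  rl$reason <- NA_character_
  idx <- match(rl$rsid, geno$variants$id)
  rl$status[is.na(idx)] <- "excluded"
  rl$reason[is.na(idx)] <- "not_in_genotypes"
  maf <- rep(NA_real_, nrow(rl))
  present <- which(!is.na(idx))
  for (i in present) {
    p <- mean(geno$dosages[, idx[i]], na.rm = TRUE) / 2
    maf[i] <- min(p, 1 - p)
  }
  low <- present[maf[present] < maf_min]
  rl$status[low] <- "excluded"
  rl$reason[low] <- "low_maf"
  # perfect LD among survivors, first-listed kept
  alive <- which(rl$status == "included")
  if (length(alive) > 1) {
    for (i in seq_along(alive)[-1]) {
      this <- alive[i]
      for (j in alive[seq_len(i - 1)]) {
        if (rl$status[j] != "included") next
        if (geno$variants$chrom[idx[this]] != geno$variants$chrom[idx[j]])
          next
        r2 <- tryCatch(ld_r2(geno$dosages[, idx[this]],
                             geno$dosages[, idx[j]]),
                       error = function(e) NA_real_)
        if (!is.na(r2) && r2 > 1 - 1e-9) {
          rl$status[this] <- "excluded"
          rl$reason[this] <- "perfect_ld"
          break
        }
      }
    }
  }
  rl
}

#' Build risk regions from included risk variants
#'
#' Each included risk variant defines a +/- `flank` bp interval; on each
#' chromosome, overlapping intervals (shared >= 1 bp) are merged
#' transitively, so a merged region spans the outermost member variants
#' +/- `flank`. Coordinates are 1-based inclusive.
#'
#' @param risk_list a screened risk list ([screen_risk_variants()]); rows
#'   with `status == "excluded"` are ignored (a list without a `status`
#'   column is taken as all included).
#' @param flank flank size in bp (default 100 kb).
#' @return data.frame: `region_id`, `chrom`, `start`, `end`,
#'   `risk_rsids` (comma-joined member variants).
#' @export
build_regions <- function(risk_list, flank = 1e5) {
  rl <- as.data.frame(risk_list, stringsAsFactors = FALSE)
  if (!is.null(rl$status)) rl <- rl[rl$status == "included", , drop = FALSE]
  if (!nrow(rl)) return(data.frame(region_id = character(),
                                   chrom = character(), start = numeric(),
                                   end = numeric(), risk_rsids = character(),
                                   stringsAsFactors = FALSE))
  out <- NULL
  for (ch in unique(rl$chrom)) {
    sub <- rl[rl$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = pmax(1, sub$pos - flank),
                           end = sub$pos + flank)
    # min.gapwidth = 0: merge on true overlap only, not mere adjacency
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red)
    members <- split(sub$rsid[S4Vectors::queryHits(hit)],
                     S4Vectors::subjectHits(hit))
    out <- rbind(out, data.frame(
      chrom = ch,
      start = IRanges::start(red),
      end = IRanges::end(red),
      risk_rsids = vapply(members, paste, "", collapse = ","),
      stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(region_id = sprintf("region_%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# single-linkage connected components over an adjacency matrix
.components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- nc
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

#' Build risk loci within regions
#'
#' Within each region, the member risk variants are clustered by
#' single linkage at LD r-squared >= `ld_threshold`; each cluster is one
#' locus (risk variants in LD are treated as a single locus with
#' multiple risk variants). A locus's LD variant set contains every
#' genotyped variant inside the region bounds whose r-squared to *any*
#' member risk variant reaches the threshold; member risk variants are
#' always in their own set. Monomorphic region variants are skipped
#' (r-squared undefined); a region whose risk variants have no dosage
#' data yields a flagged empty locus.
#'
#' @param regions output of [build_regions()].
#' @param geno the QC'd [genotype_matrix()].
#' @param ld_threshold LD membership threshold (default 0.5).
#' @return list of loci, each a list with `locus_id`, `region_id`,
#'   `chrom`, `start`, `end`, `risk_variants` (IDs), `ld_variants`
#'   (IDs incl. the risk variants), `empty` flag.
#' @export
build_loci <- function(regions, geno, ld_threshold = 0.5) {
  v <- geno$variants
  loci <- list()
  lid <- 0L
  for (ri in seq_len(nrow(regions))) {
    rg <- regions[ri, ]
    rsids <- strsplit(rg$risk_rsids, ",", fixed = TRUE)[[1]]
    idx <- match(rsids, v$id)
    if (anyNA(idx))
      stop("risk variant(s) not in genotypes: ",
           paste(rsids[is.na(idx)], collapse = ", "))
    poly <- vapply(idx, function(j)
      sd(geno$dosages[, j], na.rm = TRUE) > 0, TRUE)
    if (!any(poly)) {
      lid <- lid + 1L
      loci[[lid]] <- list(locus_id = sprintf("locus_%03d", lid),
                          region_id = rg$region_id, chrom = rg$chrom,
                          start = rg$start, end = rg$end,
                          risk_variants = rsids,
                          ld_variants = character(), empty = TRUE)
      next
    }
    rsids <- rsids[poly]; idx <- idx[poly]
    k <- length(idx)
    adj <- diag(k) > 0
    if (k > 1) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        r2 <- ld_r2(geno$dosages[, idx[a]], geno$dosages[, idx[b]])
        adj[a, b] <- adj[b, a] <- r2 >= ld_threshold
      }
    }
    comp <- .components(adj)
    in_region <- which(v$chrom == rg$chrom & v$pos >= rg$start &
                         v$pos <= rg$end)
    for (cc in sort(unique(comp))) {
      mem_idx <- idx[comp == cc]
      mem_ids <- rsids[comp == cc]
      r2max <- rep(0, length(in_region))
      for (m in mem_idx) {
        r2 <- .ld_r2_vec(geno$dosages, m, in_region)
        r2[is.na(r2)] <- 0
        r2max <- pmax(r2max, r2)
      }
      ld_ids <- union(mem_ids, v$id[in_region[r2max >= ld_threshold]])
      ld_ids <- v$id[v$id %in% ld_ids]          # genome order
      lid <- lid + 1L
      loci[[lid]] <- list(locus_id = sprintf("locus_%03d", lid),
                          region_id = rg$region_id, chrom = rg$chrom,
                          start = rg$start, end = rg$end,
                          risk_variants = mem_ids,
                          ld_variants = ld_ids, empty = FALSE)
    }
  }
  loci
}

#' Locus table
#'
#' Flattens [build_loci()] output into the tab-separated locus catalog
#' (one row per locus with its region bounds and LD variant count).
#'
#' @param loci list from [build_loci()].
#' @return data.frame: `locus_id`, `region_id`, `chrom`, `start`, `end`,
#'   `risk_rsids`, `n_risk_variants`, `n_ld_variants`.
#' @export
locus_table <- function(loci) {
  data.frame(
    locus_id = vapply(loci, `[[`, "", "locus_id"),
    region_id = vapply(loci, `[[`, "", "region_id"),
    chrom = vapply(loci, `[[`, "", "chrom"),
    start = vapply(loci, `[[`, 0, "start"),
    end = vapply(loci, `[[`, 0, "end"),
    risk_rsids = vapply(loci, function(l)
      paste(l$risk_variants, collapse = ","), ""),
    n_risk_variants = vapply(loci, function(l)
      length(l$risk_variants), 0L),
    n_ld_variants = vapply(loci, function(l)
      length(l$ld_variants), 0L),
    stringsAsFactors = FALSE)
}
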