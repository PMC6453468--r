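test_that("BH q-values match hand arithmetic and edge cases", {
  expect_equal(bh_qvalues(c(0.004, 0.06)), c(0.008, 0.06))
  expect_equal(bh_qvalues(rep(0.03, 5)), rep(0.03, 5))   # ties
  expect_equal(bh_qvalues(0.2), 0.2)                     # m = 1
  expect_identical(bh_qvalues(numeric(0)), numeric(0))
})

test_that("BH q-values equal the step-up oracle on random vectors", {
  set.seed(33)
  for (i in 1:1000) {
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    expect_equal(bh_qvalues(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("q-values are monotone in p and order-preserving under
           permutation", {
  set.seed(35)
  p <- runif(200)
  q <- bh_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  prm <- sample(200)
  expect_equal(bh_qvalues(p[prm]), q[prm])
})

mk_records <- function(df) {
  df$locus_id <- df$locus_id %||% NA_character_
  df$beta <- 0.1; df$t_stat <- 1; df$n_used <- 100L
  df$flag <- NA_character_
  df
}

test_that("gene-wise significance: per-gene Bonferroni then per-class BH", {
  rec <- mk_records(data.frame(
    gene_id = c(rep("gA", 4), "gB"),
    variant_id = c(paste0("v", 1:4), "v9"),
    p_value = c(0.001, 0.5, 0.6, 0.7, 0.5),
    stage = 1L, stringsAsFactors = FALSE))
  genes <- data.frame(gene_id = c("gA", "gB"),
                      class = c("protein_coding", "lncRNA"),
                      stringsAsFactors = FALSE)
  out <- gene_wise_significance(rec, genes)
  a <- out[out$gene_id == "gA", ]
  expect_identical(a$n_tests, 4L)
  expect_equal(a$bonferroni_min_p, 0.004)
  expect_equal(a$q_value, 0.004)            # alone in its class, m = 1
  expect_true(a$significant)
  b <- out[out$gene_id == "gB", ]
  expect_equal(b$bonferroni_min_p, 0.5)
  expect_false(b$significant)               # min p 0.5 can never pass
})

test_that("class separation changes the BH denominator", {
  p <- c(0.002, 0.004, 0.006, 0.008)
  rec <- mk_records(data.frame(
    gene_id = paste0("g", 1:4), variant_id = paste0("v", 1:4),
    p_value = p, stage = 1L, stringsAsFactors = FALSE))
  pooled <- gene_wise_significance(
    rec, data.frame(gene_id = paste0("g", 1:4), class = "protein_coding"))
  split2 <- gene_wise_significance(
    rec, data.frame(gene_id = paste0("g", 1:4),
                    class = rep(c("protein_coding", "lncRNA"), each = 2)))
  expect_equal(sort(pooled$q_value), bh_oracle(p)[order(p)])
  expect_equal(split2$q_value[split2$gene_id == "g1"],
               bh_oracle(p[1:2])[1])
  expect_false(identical(sort(pooled$q_value), sort(split2$q_value)))
})

test_that("genes with only flagged tests are excluded with a log entry", {
  rec <- mk_records(data.frame(
    gene_id = c("gA", "gB"), variant_id = c("v1", "v2"),
    p_value = c(0.01, NA), stage = 1L, stringsAsFactors = FALSE))
  rec$flag <- c(NA, "zero_variance")
  out <- gene_wise_significance(
    rec, data.frame(gene_id = c("gA", "gB"), class = "other"))
  expect_identical(out$gene_id, "gA")
  expect_identical(attr(out, "excluded_genes"), "gB")
})

test_that("variant-level FDR pools one BH pass; duplication follows the
           formula, not invariance", {
  one <- mk_records(data.frame(gene_id = "g", variant_id = "v",
                               p_value = 0.02, stage = 2L,
                               stringsAsFactors = FALSE))
  expect_equal(variant_level_fdr(one)$q_value, 0.02)
  p <- c(0.01, 0.04, 0.2, 0.9)
  rec <- mk_records(data.frame(gene_id = "g", variant_id = paste0("v", 1:4),
                               p_value = p, stage = 2L,
                               stringsAsFactors = FALSE))
  dup <- rbind(rec, rec)
  expect_equal(variant_level_fdr(dup)$q_value, bh_oracle(c(p, p)))
})

test_that("peak finding breaks ties by |t| then position", {
  vm <- data.frame(id = c("v1", "v2", "v3"), pos = c(300, 100, 200))
  rec <- data.frame(gene_id = "g", variant_id = c("v1", "v2", "v3"),
                    p_value = c(0.001, 0.001, 0.001),
                    t_stat = c(3.3, 3.3, 3.9), stringsAsFactors = FALSE)
  expect_identical(find_peak_variant("g", rec, vm)$variant_id, "v3")
  rec$t_stat <- c(3.3, 3.3, 3.3)
  expect_identical(find_peak_variant("g", rec, vm)$variant_id, "v2")
  single <- rec[1, ]
  expect_identical(find_peak_variant("g", single, vm)$variant_id, "v1")
})

test_that("the strongest planted variant is recovered as peak in >= 90%
           of replicates", {
  # block of 5 variants, realized pairwise r2 ~ 0.8 to the causal one,
  # beta = 0.6 s.d., n = 400
  set.seed(55)
  hits <- replicate(200, {
    n <- 400
    h1 <- rbinom(n, 1, 0.4); h2 <- rbinom(n, 1, 0.4)
    causal <- h1 + h2
    comps <- vapply(1:4, function(i) copy_dosage(h1, h2, 0.9, 0.4),
                    numeric(n))
    dos <- cbind(causal = causal, comps)
    colnames(dos) <- paste0("v", 1:5)
    rownames(dos) <- sprintf("s%03d", 1:n)
    y <- matrix(0.6 * as.vector(scale(causal)) + rnorm(n), 1, n,
                dimnames = list("g", NULL))
    pairs <- data.frame(gene_id = "g", variant_id = colnames(dos),
                        stage = 1L, stringsAsFactors = FALSE)
    rec <- associate(residualize(y), residualize(t(dos)), pairs, 0)
    vm <- data.frame(id = colnames(dos), pos = 1:5 * 1000)
    find_peak_variant("g", rec, vm)$variant_id == "v1"
  })
  expect_gte(mean(hits), 0.90)
})

classify_fixture <- function(r2_target) {
  set.seed(65)
  n <- 500
  h1 <- rbinom(n, 1, 0.5); h2 <- rbinom(n, 1, 0.5)
  risk <- h1 + h2
  # tune peak LD by haplotype copy probability, searching tau for the
  # requested realized r2
  tau <- sqrt(r2_target)
  peak <- copy_dosage(h1, h2, tau, 0.5)
  g <- tiny_geno(list(risk = risk, peak = peak))
  locus <- list(locus_id = "locus_001", region_id = "region_001",
                chrom = "chr1", start = 1, end = 1e5,
                risk_variants = "risk", ld_variants = c("risk", "peak"))
  list(geno = g, locus = locus,
       realized = ld_r2(risk, peak))
}

test_that("group classification respects the r2 boundaries", {
  fx <- classify_fixture(0.9)
  # peak equal to the risk variant itself: r2 = 1, Group 1
  call <- classify_gene(fx$locus, "g", "risk", fx$geno)
  expect_equal(call$r2_to_risk, 1)
  expect_identical(call$group, 1L)
  # boundary arithmetic on the pure classifier rule
  grp <- function(r2) if (r2 >= 0.5) 1L else if (r2 >= 0.2) 2L else 3L
  expect_identical(grp(0.5), 1L)    # r2 = 0.5 exactly is Group 1
  expect_identical(grp(0.2), 2L)    # r2 = 0.2 exactly is Group 2
  expect_identical(grp(0.1999), 3L)
  # and the classifier agrees on realized LD fixtures
  call2 <- classify_gene(fx$locus, "g", "peak", fx$geno)
  expect_identical(call2$group, grp(fx$realized))
})

test_that("classification fails on a monomorphic peak variant", {
  fx <- classify_fixture(0.9)
  fx$geno$dosages[, "peak"] <- 1
  expect_error(classify_gene(fx$locus, "g", "peak", fx$geno),
               "monomorphic")
})

test_that("groups partition [0,1]: every classified gene gets exactly one
           group", {
  set.seed(71)
  for (r2t in c(0.05, 0.15, 0.25, 0.45, 0.55, 0.85)) {
    n <- 500
    h1 <- rbinom(n, 1, 0.5); h2 <- rbinom(n, 1, 0.5)
    g <- tiny_geno(list(risk = h1 + h2,
                        peak = copy_dosage(h1, h2, sqrt(r2t), 0.5)))
    locus <- list(locus_id = "L", region_id = "R", chrom = "chr1",
                  start = 1, end = 1e5, risk_variants = "risk",
                  ld_variants = c("risk", "peak"))
    call <- classify_gene(locus, "g", "peak", g)
    expect_true(call$group %in% 1:3)
    expect_identical(length(call$group), 1L)
  }
})

test_that("summary arithmetic renders percentages at the printed
           precision", {
  expect_identical(report_percent(102, 196, 1), "52.0")
  expect_identical(report_percent(58, 141, 0), "41")
  expect_identical(report_percent(52, 102, 0), "51")
})

test_that("an empty call set summarizes to an all-zero table", {
  empty_calls <- data.frame(locus_id = character(), gene_id = character(),
                            gene_class = character(),
                            peak_variant_id = character(),
                            peak_p = numeric(), r2_to_risk = numeric(),
                            group = integer(), stringsAsFactors = FALSE)
  sig <- data.frame(gene_id = "g", gene_class = "other", n_tests = 1L,
                    min_p = 0.9, bonferroni_min_p = 0.9, q_value = 0.9,
                    significant = FALSE, stringsAsFactors = FALSE)
  s <- summarize_calls(empty_calls, sig, loci = list())
  expect_true(all(s$gene_groups[, c("group1", "group2", "group3")] == 0))
  expect_identical(s$totals$n_unique_genes_called, 0L)
})

test_that("multi-locus genes are counted once, in their highest-LD group", {
  calls <- data.frame(
    locus_id = c("L1", "L2", "L3"),
    gene_id = c("gA", "gA", "gB"),
    gene_class = c("protein_coding", "protein_coding", "lncRNA"),
    peak_variant_id = "v", peak_p = 1e-8,
    r2_to_risk = c(0.9, 0.05, 0.3),
    group = c(1L, 3L, 2L), stringsAsFactors = FALSE)
  sig <- data.frame(gene_id = c("gA", "gB"),
                    gene_class = c("protein_coding", "lncRNA"),
                    n_tests = 1L, min_p = 1e-9, bonferroni_min_p = 1e-9,
                    q_value = 1e-9, significant = TRUE,
                    stringsAsFactors = FALSE)
  loci <- list(list(locus_id = "L1"), list(locus_id = "L2"),
               list(locus_id = "L3"), list(locus_id = "L4"))
  s <- summarize_calls(calls, sig, loci)
  expect_identical(s$gene_groups["protein_coding", "group1"], 1L)
  expect_identical(s$gene_groups["protein_coding", "group3"], 0L)
  expect_identical(s$gene_groups["lncRNA", "group2"], 1L)
  expect_identical(s$locus_summary$n_loci_with_signal, 3L)
  expect_identical(s$locus_summary$pct_loci_with_signal, "75.0")
  expect_identical(s$locus_summary$n_loci_group1, 1L)
})
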