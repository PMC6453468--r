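test_that("intercept-only residualization is row centering", {
  set.seed(2)
  m <- matrix(rnorm(50, 5), 5, 10)
  expect_equal(residualize(m), m - rowMeans(m))
})

test_that("a row equal to a covariate residualizes to zero", {
  set.seed(4)
  X <- cbind(cov1 = rnorm(30), cov2 = runif(30))
  m <- rbind(X[, "cov1"], rnorm(30))
  r <- residualize(m, X)
  expect_lt(sqrt(sum(r[1, ]^2)), 1e-10)
})

test_that("projection residuals equal per-row least-squares residuals", {
  set.seed(6)
  X <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(NULL, paste0("c", 1:3)))
  m <- matrix(rnorm(8 * 40), 8, 40)
  r <- residualize(m, X)
  for (i in 1:8)
    expect_equal(unname(r[i, ]), unname(resid(lm(m[i, ] ~ X))),
                 tolerance = 1e-10)
})

test_that("a rank-deficient design fails naming the collinear column", {
  X <- cbind(a = rnorm(20), b = 1:20, dup = 2 * (1:20))
  expect_error(residualize(matrix(rnorm(20), 1), X), "dup")
})

test_that("residualize-then-correlate reproduces full multiple regression
           (Frisch-Waugh-Lovell)", {
  set.seed(8)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("c", 1:4)))
  expr <- matrix(rnorm(20 * n), 20, n,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  geno <- matrix(rbinom(15 * n, 2, 0.3), 15, n,
                 dimnames = list(sprintf("v%02d", 1:15), NULL))
  pairs <- expand.grid(gene_id = rownames(expr), variant_id = rownames(geno),
                       stringsAsFactors = FALSE)
  pairs$stage <- 1L
  rec <- associate(residualize(expr, X), residualize(geno, X), pairs,
                   n_covariates = 4)
  for (i in sample(nrow(rec), 60)) {
    o <- lm_oracle(expr[rec$gene_id[i], ], geno[rec$variant_id[i], ], X)
    expect_equal(rec$t_stat[i], o$t, tolerance = 1e-8)
    expect_equal(rec$beta[i], o$beta, tolerance = 1e-8)
    expect_equal(rec$p_value[i], o$p, tolerance = 1e-8)
  }
})

test_that("monomorphic-after-residualization pairs are flagged, no p", {
  n <- 30
  expr <- matrix(rnorm(n), 1, n, dimnames = list("g1", NULL))
  geno <- matrix(1, 1, n, dimnames = list("v1", NULL))
  pairs <- data.frame(gene_id = "g1", variant_id = "v1", stage = 1L)
  rec <- associate(residualize(expr), residualize(geno), pairs, 0)
  expect_identical(rec$flag, "zero_variance")
  expect_true(is.na(rec$p_value))
})

test_that("null associations are uniform and hold 5% type-I error", {
  set.seed(10)
  n <- 150
  expr <- matrix(rnorm(100 * n), 100, n,
                 dimnames = list(sprintf("g%03d", 1:100), NULL))
  geno <- matrix(rbinom(100 * n, 2, 0.35), 100, n,
                 dimnames = list(sprintf("v%03d", 1:100), NULL))
  pairs <- expand.grid(gene_id = rownames(expr),
                       variant_id = rownames(geno),
                       stringsAsFactors = FALSE)
  pairs$stage <- 1L
  rec <- associate(residualize(expr), residualize(geno), pairs, 0)
  expect_identical(nrow(rec), 10000L)
  ks <- suppressWarnings(ks.test(rec$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(rec$p_value < 0.05) - 0.05), 0.01)
})

test_that("statistics are invariant under a shared sample permutation", {
  set.seed(12)
  n <- 60
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  expr <- matrix(rnorm(5 * n), 5, n,
                 dimnames = list(sprintf("g%d", 1:5), NULL))
  geno <- matrix(rbinom(5 * n, 2, 0.4), 5, n,
                 dimnames = list(sprintf("v%d", 1:5), NULL))
  pairs <- expand.grid(gene_id = rownames(expr),
                       variant_id = rownames(geno),
                       stringsAsFactors = FALSE)
  pairs$stage <- 1L
  base <- associate(residualize(expr, X), residualize(geno, X), pairs, 2)
  prm <- sample(n)
  perm <- associate(residualize(expr[, prm], X[prm, ]),
                    residualize(geno[, prm], X[prm, ]), pairs, 2)
  expect_equal(base$t_stat, perm$t_stat, tolerance = 1e-10)
  expect_equal(base$p_value, perm$p_value, tolerance = 1e-10)
})

test_that("a planted 0.6 s.d. effect at n = 400 clears |t| > 5", {
  rep <- run_recovery_rep(seed = 61, tags = "self")
  st <- rep$study
  rec <- rep$result$records1
  hit <- rec[rec$gene_id == st$truth$causal_pairs$gene_id &
               rec$variant_id == st$truth$causal_pairs$variant_id, ]
  expect_identical(nrow(hit), 1L)
  expect_gt(abs(hit$t_stat), 5)
  expect_lt(hit$p_value, 1e-6)
})

stage_fixture <- function() {
  v <- 5e6                                 # variant position
  genes <- data.frame(
    gene_id = c("at_edge", "inside", "too_far", "other_chr"),
    class = "protein_coding",
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    tss = c(v + 1.1e6, v - 2e4, v + 1.2e6, v),
    tes = c(v + 1.1e6 + 1e4, v + 2e4, v + 1.25e6, v + 1e4),
    gc_fraction = 0.5, stringsAsFactors = FALSE)
  loci <- list(list(locus_id = "locus_001", region_id = "region_001",
                    chrom = "chr1", start = v - 1e5, end = v + 1e5,
                    risk_variants = "rv", ld_variants = "rv",
                    ld_positions = list(rv = v), empty = FALSE))
  list(genes = genes, loci = loci, v = v)
}

test_that("stage-1 eligibility is span distance <= 1.1 Mb, boundary
           inclusive", {
  fx <- stage_fixture()
  p <- stage1_pairs(fx$loci, fx$genes)
  expect_setequal(p$gene_id, c("at_edge", "inside"))
  expect_identical(unique(p$locus_id), "locus_001")
})

test_that("stage-2 windows are [TSS - 1.1 Mb, TES + 1.1 Mb], inclusive", {
  fx <- stage_fixture()
  n <- 10
  pos <- c(fx$v - 1.1e6 - 2e4,             # just below window
           fx$v - 1.1e6 - 2e4 + 1,         # still below (gene at_edge)
           seq(fx$v, fx$v + 2.21e6, length.out = 6),
           fx$v + 1.1e6 + 1e4 + 1e6)
  pos <- sort(round(pos))
  dos <- matrix(rbinom(20 * length(pos), 2, 0.4), 20, length(pos))
  colnames(dos) <- sprintf("w%02d", seq_along(pos))
  rownames(dos) <- sprintf("s%03d", 1:20)
  g <- genotype_matrix(dos, data.frame(
    id = colnames(dos), chrom = "chr1", pos = pos,
    stringsAsFactors = FALSE))
  target <- fx$genes[fx$genes$gene_id == "at_edge", ]
  p <- stage2_pairs(target, g)
  lo <- target$tss - 1.1e6; hi <- target$tes + 1.1e6
  expect_setequal(p$variant_id, g$variants$id[pos >= lo & pos <= hi])
  # boundary variants exactly at the window edges are included
  m2 <- dos[, 1:2]
  colnames(m2) <- c("lo_edge", "hi_edge")
  g2 <- genotype_matrix(m2,
                        data.frame(id = c("lo_edge", "hi_edge"),
                                   chrom = "chr1", pos = c(lo, hi),
                                   stringsAsFactors = FALSE))
  expect_setequal(stage2_pairs(target, g2)$variant_id,
                  c("lo_edge", "hi_edge"))
  # other chromosomes are never paired
  g3 <- genotype_matrix(dos[, 1, drop = FALSE],
                        data.frame(id = "w01", chrom = "chr9",
                                   pos = target$tss,
                                   stringsAsFactors = FALSE))
  expect_identical(nrow(stage2_pairs(target, g3)), 0L)
})

test_that("a gene with 50 in-window variants yields exactly 50 pairs", {
  set.seed(14)
  pos <- sort(sample.int(2e6, 50)) + 4e6
  dos <- matrix(rbinom(30 * 50, 2, 0.3), 30, 50,
                dimnames = list(sprintf("s%03d", 1:30),
                                sprintf("v%02d", 1:50)))
  g <- genotype_matrix(dos, data.frame(id = colnames(dos), chrom = "chr1",
                                       pos = pos, stringsAsFactors = FALSE))
  target <- data.frame(gene_id = "g", class = "protein_coding",
                       chrom = "chr1", tss = 5e6, tes = 5.01e6,
                       gc_fraction = 0.5, stringsAsFactors = FALSE)
  expect_identical(nrow(stage2_pairs(target, g)), 50L)
})
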