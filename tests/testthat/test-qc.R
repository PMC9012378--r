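test_that("call rate counts non-missing genotypes", {
  gm <- random_gm(10, 3, seed = 1)
  expect_equal(unname(call_rate(gm)), rep(1, 3))
  gm$dosages[4, 2] <- NA
  expect_equal(call_rate(gm, "v002"), 0.9)
  m <- is.na(random_gm(50, 5, missing_rate = 0.3, seed = 2)$dosages)
  gm2 <- random_gm(50, 5, missing_rate = 0.3, seed = 2)
  expect_equal(unname(call_rate(gm2)), colSums(!is.na(gm2$dosages)) / 50,
               ignore_attr = TRUE)
  expect_error(call_rate(gm, "nope"), "unknown vid")
})

test_that("MAF folds to the minor allele and is relabeling-invariant", {
  base <- random_gm(4, 3, seed = 5)
  gm <- base
  gm$dosages[, 1] <- c(0, 0, 0, 0)
  gm$dosages[, 2] <- c(2, 2, 2, 2)
  gm$dosages[, 3] <- c(0, 1, 1, 2)
  expect_equal(unname(maf(gm)), c(0, 0, 0.5))
  # invariance under g -> 2 - g
  gm2 <- random_gm(30, 6, missing_rate = 0.1, seed = 6)
  gm3 <- gm2; gm3$dosages <- 2 - gm3$dosages
  expect_equal(maf(gm2), maf(gm3))
})

test_that("HWE exact p-value matches enumeration on pinned cases", {
  expect_equal(hwe_exact_p(25, 50, 25), 1)      # modal configuration
  expect_equal(hwe_exact_p(0, 0, 10), 1)        # monomorphic
  expect_equal(hwe_exact_p(10, 0, 10), oracle_hwe(10, 0, 10),
               tolerance = 1e-12)
  # strong het deficit is significant
  expect_lt(hwe_exact_p(50, 0, 50), 1e-20)
  expect_error(hwe_exact_p(-1, 2, 3), ">= 0")
})

test_that("HWE exact p-value equals enumeration over a sampled grid", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(1:50, 1)
    aa <- sample(0:n, 1); ab <- sample(0:(n - aa), 1)
    expect_equal(hwe_exact_p(aa, ab, n - aa - ab),
                 oracle_hwe(aa, ab, n - aa - ab), tolerance = 1e-12)
  }
})

test_that("ld_r2 is squared correlation over jointly observed samples", {
  gm <- random_gm(30, 4, seed = 8)
  gm$dosages[, 2] <- gm$dosages[, 1]
  expect_equal(ld_r2(gm, "v001", "v002"), 1)
  gm$dosages[, 3] <- 2 - gm$dosages[, 1]       # r = -1, r2 = 1
  expect_equal(ld_r2(gm, "v001", "v003"), 1)
  gm$dosages[c(3, 7), 4] <- NA
  ok <- !is.na(gm$dosages[, 4])
  expect_equal(ld_r2(gm, "v001", "v004"),
               cor(gm$dosages[ok, 1], gm$dosages[ok, 4])^2,
               tolerance = 1e-12)
  gm$dosages[, 4] <- 1
  expect_error(ld_r2(gm, "v001", "v004"), "monomorphic")
})

test_that("apply_qc keeps exactly the variants passing every filter", {
  # 6 variants: 2 fail call rate, 1 fails MAF, 1 fails HWE, 2 survive
  n <- 100
  set.seed(3)
  dos <- cbind(rbinom(n, 2, 0.3),                       # pass
               rbinom(n, 2, 0.4),                       # pass
               rbinom(n, 2, 0.3),                       # fail call rate
               rbinom(n, 2, 0.3),                       # fail call rate
               rbinom(n, 2, 0.001),                     # fail MAF
               c(rep(0, 50), rep(2, 50)))               # fail HWE
  dos[1:10, 3] <- NA
  dos[1:6, 4] <- NA
  pairs <- rbind(c("A", "G"), c("T", "C"), c("A", "C"),
                 c("T", "G"), c("A", "G"), c("C", "T"))
  gm <- genotype_matrix(dos,
    data.frame(chrom = "1", pos = 1:6 * 10L, vid = paste0("q", 1:6),
               allele_a = pairs[, 1], allele_b = pairs[, 2]),
    sprintf("s%03d", 1:n))
  res <- apply_qc(gm, qc_thresholds())
  expect_setequal(res$genotypes$variants$vid, c("q1", "q2"))
  expect_equal(res$report$fail_reason,
               c("", "", "call_rate", "call_rate", "maf", "hwe"))

  # thresholds of zero keep everything
  res0 <- apply_qc(gm, qc_thresholds(0, 0, 0, 1))
  expect_true(all(res0$report$pass))
  # an unattainable MAF bound empties the output with a warning
  expect_warning(res1 <- apply_qc(gm, qc_thresholds(0, 0.51, 0, 1)),
                 "no variants pass")
  expect_equal(ncol(res1$genotypes$dosages), 0)
})

test_that("apply_qc survivors are independent of variant order", {
  gm <- random_gm(80, 12, missing_rate = 0.08, seed = 13)
  perm <- sample(12)
  gmp <- subset_genotypes(gm, vids = gm$variants$vid[perm])
  a <- apply_qc(gm, qc_thresholds(0.9, 0.05, 1e-6, 0.8))
  b <- apply_qc(gmp, qc_thresholds(0.9, 0.05, 1e-6, 0.8))
  expect_setequal(a$genotypes$variants$vid, b$genotypes$variants$vid)
})

test_that("controls-only HWE uses only control samples", {
  gm <- random_gm(60, 3, seed = 30)
  cohort <- cohort_table(data.frame(
    sample_id = gm$sample_ids,
    label = rep(c("case", "control"), each = 30),
    cohort = rep(c("A", "control"), each = 30)))
  # het-free cases would wreck the all-sample HWE p for variant 1
  gm$dosages[1:30, 1] <- rep(c(0, 2), 15)
  gm$dosages[31:60, 1] <- rbinom(30, 2, 0.5)
  r_all <- apply_qc(gm, qc_thresholds(), "all")$report
  r_ctl <- apply_qc(gm, qc_thresholds(), "controls", cohort)$report
  g <- gm$dosages[31:60, 1]
  expect_equal(r_ctl$hwe_p[1],
               hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2)))
  expect_true(r_ctl$hwe_p[1] != r_all$hwe_p[1])
})

test_that("LD pruning drops duplicates and keeps independent variants", {
  gm <- random_gm(100, 5, seed = 17)
  gm$dosages[, 2] <- gm$dosages[, 1]            # duplicate of v001
  kept <- ld_prune(gm, 0.8)
  expect_false("v002" %in% kept)
  expect_true("v001" %in% kept)

  # mutually independent simulated sites are all kept
  gm2 <- random_gm(500, 20, seed = 18)
  expect_equal(ld_prune(gm2, 0.8), gm2$variants$vid)

  # kept set satisfies the pairwise bound exhaustively
  gm3 <- random_gm(60, 15, seed = 19)
  gm3$dosages[, 4] <- gm3$dosages[, 3]
  gm3$dosages[, 9] <- pmin(2, gm3$dosages[, 8] + rbinom(60, 1, 0.05))
  kept3 <- ld_prune(gm3, 0.5)
  for (a in seq_along(kept3)) for (b in seq_len(a - 1))
    expect_lte(ld_r2(gm3, kept3[b], kept3[a]), 0.5)
})

test_that("ld_prune(1) keeps all; ld_prune(0) collapses perfect clusters", {
  gm <- random_gm(80, 8, seed = 23)
  gm$dosages[, 5] <- gm$dosages[, 2]
  expect_equal(ld_prune(gm, 1.0), gm$variants$vid)
  kept0 <- ld_prune(gm, 0.0)
  expect_false(all(c("v002", "v005") %in% kept0))
})

test_that("genotype PCA separates two simulated subpopulations", {
  set.seed(31)
  m <- 60
  maf1 <- runif(m, 0.05, 0.5)
  maf2 <- pmin(0.5, pmax(0.02, maf1 + sample(c(-1, 1), m, TRUE) * 0.3))
  dos <- rbind(matrix(rbinom(50 * m, 2, rep(maf1, each = 50)), 50, m),
               matrix(rbinom(50 * m, 2, rep(maf2, each = 50)), 50, m))
  gm <- genotype_matrix(dos,
    data.frame(chrom = "1", pos = 1:m * 10L, vid = sprintf("p%03d", 1:m),
               allele_a = "A", allele_b = "G"),
    sprintf("s%03d", 1:100))
  sc <- genotype_pca(gm, 2)
  pc1 <- sc[, 1]
  g1 <- pc1[1:50]; g2 <- pc1[51:100]
  pooled_sd <- sqrt((var(g1) + var(g2)) / 2)
  expect_gt(abs(mean(g1) - mean(g2)), 4 * pooled_sd)
  # zero overlap between the two clusters along PC1
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))
})

test_that("PCA reconstruction matches the SVD optimum and k=0 works", {
  gm <- random_gm(25, 10, seed = 33)
  expect_equal(ncol(genotype_pca(gm, 0)), 0)
  k <- 3
  sc <- genotype_pca(gm, k)
  rot <- attr(sc, "rotation")
  x <- scale(gm$dosages)
  sv <- svd(x)
  best <- sv$u[, 1:k] %*% diag(sv$d[1:k]) %*% t(sv$v[, 1:k])
  err_pca <- sum((x - sc %*% t(rot))^2)
  err_svd <- sum((x - best)^2)
  expect_equal(err_pca, err_svd, tolerance = 1e-8)
})
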