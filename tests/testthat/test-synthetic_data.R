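test_that("genotype simulation is seed-deterministic and HWE-consistent", {
  cfg <- simulation_config(seed = 101, missing_rate = 0)
  g1 <- simulate_genotypes(cfg, 200)
  g2 <- simulate_genotypes(cfg, 200)
  expect_identical(g1$dosages, g2$dosages)
  expect_equal(unname(call_rate(g1)), rep(1, 31))

  cfg2 <- simulation_config(n_variants = 200, seed = 102, missing_rate = 0)
  gm <- simulate_genotypes(cfg2, 10000)
  hp <- apply(gm$dosages, 2, function(g)
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2)))
  expect_gte(mean(hp >= 1e-6), 0.99)
})

test_that("missing injection matches the configured rate", {
  cfg <- simulation_config(seed = 103, missing_rate = 0.2)
  gm <- simulate_genotypes(cfg, 2000)
  expect_lt(abs(mean(is.na(gm$dosages)) - 0.2), 0.01)
})

test_that("a null panel yields chance-level discrimination", {
  cfg <- simulation_config(true_weights = rep(0, 31),
                           n_cases_a = 1000, n_cases_b = 10,
                           n_controls = 1000,
                           covariate_effects = c(age = 0, sex = 0,
                                                 hypertension = 0,
                                                 diabetes = 0,
                                                 hyperlipidemia = 0,
                                                 smoking = 0),
                           missing_rate = 0, seed = 104)
  sim <- simulate_case_control(cfg)
  wt <- sim$weights; wt$weight <- rep(1, 31)  # unweighted allele count
  sel <- sim$cohort$cohort %in% c("A", "control")
  gm <- subset_genotypes(sim$genotypes,
                         sample_ids = sim$cohort$sample_id[sel])
  sc <- weighted_prs(gm, wt, mode = "sum")
  a <- auroc(sim$cohort$label[sel] == "case", sc$wprs)$auroc
  expect_gte(a, 0.45); expect_lte(a, 0.55)
})

test_that("empirical AUROC matches the binormal closed form", {
  cfg <- simulation_config(n_cases_a = 800, n_cases_b = 10,
                           n_controls = 800,
                           covariate_effects = c(age = 0, sex = 0,
                                                 hypertension = 0,
                                                 diabetes = 0,
                                                 hyperlipidemia = 0,
                                                 smoking = 0),
                           missing_rate = 0, seed = 105)
  sim <- simulate_case_control(cfg)
  sel <- sim$cohort$cohort %in% c("A", "control")
  gm <- subset_genotypes(sim$genotypes,
                         sample_ids = sim$cohort$sample_id[sel])
  sc <- weighted_prs(gm, sim$weights, mode = "sum")
  case <- sim$cohort$label[sel] == "case"
  x <- sc$wprs[case]; y <- sc$wprs[!case]
  delta <- (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)
  expect_equal(auroc(case, sc$wprs)$auroc, pnorm(delta / sqrt(2)),
               tolerance = 0.02)
})

test_that("per-variant effects are recovered by an adjusted joint refit", {
  cfg <- simulation_config(n_cases_a = 4000, n_cases_b = 10,
                           n_controls = 4000, missing_rate = 0,
                           shared_effect_fraction = 0, seed = 106)
  sim <- simulate_case_control(cfg)
  sel <- sim$cohort$cohort %in% c("A", "control")
  co <- sim$cohort[sel, ]
  gm <- subset_genotypes(sim$genotypes, sample_ids = co$sample_id)
  X <- cbind(gm$dosages,
             age = co$age - 60, sex = co$sex,
             hypertension = co$hypertension, diabetes = co$diabetes,
             hyperlipidemia = co$hyperlipidemia, smoking = co$smoking)
  fit <- fit_logistic(co$label, X, firth = "never")
  bhat <- fit$coef[gm$variants$vid]
  bias <- mean(bhat - sim$truth$beta_a)
  expect_lt(abs(bias), 0.05)
})

test_that("stronger effects never reduce median discrimination", {
  med_auc <- sapply(c(0.4, 1, 2.5), function(scale) {
    aucs <- sapply(1:8, function(r) {
      cfg <- simulation_config(
        true_weights = scale * abs(0.5 + 0.2 * sin(1:31)),
        n_cases_a = 120, n_cases_b = 10, n_controls = 120,
        missing_rate = 0, seed = 200 + r)
      sim <- simulate_case_control(cfg)
      sel <- sim$cohort$cohort %in% c("A", "control")
      gm <- subset_genotypes(sim$genotypes,
                             sample_ids = sim$cohort$sample_id[sel])
      sc <- weighted_prs(gm, sim$weights, mode = "sum")
      auroc(sim$cohort$label[sel] == "case", sc$wprs)$auroc
    })
    median(aucs)
  })
  expect_true(all(diff(med_auc) >= 0))
})

test_that("cross-disease validation tracks the shared-effect fraction", {
  auc_pair <- function(frac, seed) {
    cfg <- simulation_config(shared_effect_fraction = frac,
                             missing_rate = 0, seed = seed)
    sim <- simulate_case_control(cfg)
    sapply(c("A", "B"), function(tag) {
      sel <- sim$cohort$cohort %in% c(tag, "control")
      gm <- subset_genotypes(sim$genotypes,
                             sample_ids = sim$cohort$sample_id[sel])
      sc <- weighted_prs(gm, sim$weights, mode = "sum")
      auroc(sim$cohort$label[sel] == "case", sc$wprs)$auroc
    })
  }
  full <- auc_pair(1, 301)
  expect_lt(abs(full["A"] - full["B"]), 0.06)   # fully shared panel
  none <- auc_pair(0, 302)
  expect_lt(abs(none["B"] - 0.5), 0.08)         # disjoint architecture
  expect_gt(none["A"], none["B"])
})

test_that("fixture bundles are reproducible and internally consistent", {
  cfg <- simulation_config(n_cases_a = 60, n_cases_b = 50,
                           n_controls = 70, missing_rate = 0.2,
                           seed = 400)
  d1 <- file.path(withr::local_tempdir(), "b1")
  d2 <- file.path(withr::local_tempdir(), "b2")
  m1 <- make_fixture_bundle(cfg, d1)
  m2 <- make_fixture_bundle(cfg, d2)
  expect_equal(m1$md5, m2$md5)

  # pipeline re-run on the bundle matches the bundled double-loop scores
  gm <- read_plink(file.path(d1, "genotypes"))
  wt <- read_weight_table(file.path(d1, "weights.tsv"))
  expected <- read.delim(file.path(d1, "expected_scores.tsv"))
  sc <- weighted_prs(harmonize(gm, wt)$genotypes, wt, mode = "average")
  expect_equal(sc$wprs, expected$wprs, tolerance = 1e-10)

  # imputation bookkeeping equals the injected missing count
  expect_equal(sum(sc$n_imputed_cells), sum(is.na(gm$dosages)))

  # the VCF and PLINK encodings carry identical genotypes
  gv <- read_vcf(file.path(d1, "genotypes.vcf"))
  expect_equal(gv$dosages, gm$dosages)
})
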