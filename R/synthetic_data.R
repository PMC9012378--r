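#' Simulation configuration for synthetic case-control cohorts
#'
#' Defaults mirror a two-disease shared-control design: a 31-variant
#' panel (29 genome-wide-significant "gwas" variants plus 2 "reported"
#' variants), 250 cases of disease A, 222 cases of disease B and 296
#' shared controls. Disease liabilities are additive on the log-odds
#' scale with covariate effects; disease B shares a configurable fraction
#' of disease A's non-zero variant effects.
#'
#' @param n_variants panel size.
#' @param maf_range interval the per-variant minor allele frequencies are
#'   drawn from (uniform).
#' @param true_weights optional numeric vector of per-variant log-odds
#'   for disease A; by default 29 are drawn as `|N(0.5, 0.2^2)|`
#'   ("gwas") and the last 2 as `|N(0.2, 0.05^2)|` ("reported").
#' @param n_cases_a,n_cases_b,n_controls cohort sizes.
#' @param shared_effect_fraction fraction of disease A's non-zero effects
#'   that also act on disease B (the rest are zero for B).
#' @param prevalence length-2 vector: target population prevalence of
#'   diseases A and B; each intercept is tuned by bisection to this
#'   marginal case probability. Kept at a realistic few percent so that
#'   screening the shared controls for freedom from both diseases barely
#'   perturbs their genotype distribution.
#' @param covariate_effects named log-odds effects of
#'   `age` (per year, centered), `sex`, `hypertension`, `diabetes`,
#'   `hyperlipidemia`, `smoking` applied to both liabilities.
#' @param missing_rate per-cell missing genotype probability.
#' @param seed integer seed; mandatory for reproducibility.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_variants = 31,
                              maf_range = c(0.05, 0.5),
                              true_weights = NULL,
                              n_cases_a = 250, n_cases_b = 222,
                              n_controls = 296,
                              shared_effect_fraction = 0.7,
                              prevalence = c(0.05, 0.05),
                              covariate_effects = c(age = 0.02, sex = 0.3,
                                                    hypertension = 0.5,
                                                    diabetes = 0.3,
                                                    hyperlipidemia = 0.2,
                                                    smoking = 0.3),
                              missing_rate = 0.01,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_variants >= 1, n_cases_a >= 1, n_cases_b >= 1,
            n_controls >= 1,
            shared_effect_fraction >= 0, shared_effect_fraction <= 1,
            length(prevalence) == 2, all(prevalence > 0 & prevalence < 1),
            missing_rate >= 0, missing_rate <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(n_variants = n_variants, maf_range = maf_range,
                 true_weights = true_weights, n_cases_a = n_cases_a,
                 n_cases_b = n_cases_b, n_controls = n_controls,
                 shared_effect_fraction = shared_effect_fraction,
                 prevalence = prevalence,
                 covariate_effects = covariate_effects,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

# non-palindromic biallelic SNP alleles, so harmonization keeps everything
draw_alleles <- function(m) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]
}

make_panel <- function(cfg) {
  m <- cfg$n_variants
  w <- cfg$true_weights
  if (is.null(w)) {
    n_rep <- min(2, m)
    w <- c(abs(stats::rnorm(m - n_rep, 0.5, 0.2)),
           abs(stats::rnorm(n_rep, 0.2, 0.05)))
  }
  if (length(w) != m) stop("true_weights length must equal n_variants")
  al <- draw_alleles(m)
  list(variants = data.frame(
         chrom = as.character(rep_len(1:22, m)[order(rep_len(1:22, m))]),
         pos = 1000L * seq_len(m),
         vid = sprintf("var%04d", seq_len(m)),
         allele_a = al[, 1], allele_b = al[, 2],
         stringsAsFactors = FALSE),
       weights = w,
       mafs = stats::runif(m, cfg$maf_range[1], cfg$maf_range[2]),
       source = c(rep("gwas", m - min(2, m)), rep("reported", min(2, m))))
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Draws per-variant minor allele frequencies uniformly from
#' `cfg$maf_range`, then genotype dosages as Binomial(2, p) (the HWE
#' proportions p^2 / 2pq / q^2), and finally injects missing cells
#' uniformly at random at `cfg$missing_rate`.
#'
#' @param cfg a [simulation_config()].
#' @param n number of samples.
#' @param seed seed (defaults to `cfg$seed`).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg, n, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed)
  panel <- make_panel(cfg)
  m <- cfg$n_variants
  dos <- matrix(stats::rbinom(n * m, 2,
                              rep(panel$mafs, each = n)), n, m)
  if (cfg$missing_rate > 0)
    dos[stats::runif(n * m) < cfg$missing_rate] <- NA
  genotype_matrix(dos, panel$variants, sprintf("S%05d", seq_len(n)))
}

draw_covariates <- function(n) {
  data.frame(age = round(pmax(18, stats::rnorm(n, 60, 13)), 1),
             sex = stats::rbinom(n, 1, 0.5),
             hypertension = stats::rbinom(n, 1, 0.35),
             diabetes = stats::rbinom(n, 1, 0.2),
             hyperlipidemia = stats::rbinom(n, 1, 0.3),
             smoking = stats::rbinom(n, 1, 0.25))
}

cov_logit <- function(cov, gamma) {
  drop(as.matrix(
    data.frame(age = cov$age - 60, cov[, c("sex", "hypertension",
                                           "diabetes", "hyperlipidemia",
                                           "smoking")])) %*%
      gamma[c("age", "sex", "hypertension", "diabetes", "hyperlipidemia",
              "smoking")])
}

# bisection for the intercept giving a target marginal case probability
tune_alpha <- function(target, lin, lo = -50, hi = 50, iter = 60) {
  f <- function(a) mean(stats::plogis(a + lin)) - target
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Simulate two case cohorts with shared controls
#'
#' Generates genotypes and covariates for a population, computes two
#' additive log-odds disease liabilities (disease B keeps a
#' `shared_effect_fraction` of disease A's variant effects, the rest set
#' to zero), tunes each intercept by bisection so the marginal case
#' probability matches the configured prevalence, and fills each cohort
#' by rejection sampling from its own independent population draws:
#' disease-A cases, disease-B cases, and controls free of both diseases.
#'
#' @param cfg a [simulation_config()].
#' @param seed seed (defaults to `cfg$seed`).
#' @return A list: `genotypes` ([genotype_matrix()] over all samples),
#'   `cohort` ([cohort_table()] with cohorts `"A"`, `"B"`,
#'   `"control"`), `weights` (the disease-A [weight_table()]), and
#'   `truth` (list with `beta_a`, `beta_b`, `alpha_a`, `alpha_b`,
#'   `mafs`).
#' @export
simulate_case_control <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed)
  panel <- make_panel(cfg)
  m <- cfg$n_variants
  beta_a <- panel$weights
  n_shared <- round(cfg$shared_effect_fraction * m)
  beta_b <- beta_a
  if (n_shared < m) beta_b[seq.int(n_shared + 1, m)] <- 0

  frac_a <- cfg$prevalence[1]
  frac_b <- cfg$prevalence[2]

  # tune intercepts on a reference draw from the population model
  n_ref <- 20000
  gref <- matrix(stats::rbinom(n_ref * m, 2, rep(panel$mafs, each = n_ref)),
                 n_ref, m)
  cref <- draw_covariates(n_ref)
  cl <- cov_logit(cref, cfg$covariate_effects)
  alpha_a <- tune_alpha(frac_a, drop(gref %*% beta_a) + cl)
  alpha_b <- tune_alpha(frac_b, drop(gref %*% beta_b) + cl)

  # each cohort is rejection-sampled from its own independent population
  # draws, so case genotypes follow P(g | disease) and controls
  # P(g | disease-free), with no cross-cohort selection artifacts
  fill <- function(need, keep_fn) {
    got_g <- list(); got_c <- list(); count <- 0L
    batch <- max(2000L, need)
    for (it in 1:200) {
      g <- matrix(stats::rbinom(batch * m, 2, rep(panel$mafs, each = batch)),
                  batch, m)
      cov <- draw_covariates(batch)
      cl <- cov_logit(cov, cfg$covariate_effects)
      take <- utils::head(which(keep_fn(g, cl)), need - count)
      if (length(take)) {
        got_g <- c(got_g, list(g[take, , drop = FALSE]))
        got_c <- c(got_c, list(cov[take, , drop = FALSE]))
        count <- count + length(take)
      }
      if (count >= need) break
    }
    if (count < need)
      stop("could not reach configured cohort sizes within the iteration budget")
    list(g = do.call(rbind, got_g), cov = do.call(rbind, got_c))
  }
  p_a <- function(g, cl) stats::plogis(alpha_a + drop(g %*% beta_a) + cl)
  p_b <- function(g, cl) stats::plogis(alpha_b + drop(g %*% beta_b) + cl)
  pa <- fill(cfg$n_cases_a,
             function(g, cl) stats::runif(nrow(g)) < p_a(g, cl))
  pb <- fill(cfg$n_cases_b,
             function(g, cl) stats::runif(nrow(g)) < p_b(g, cl))
  pc <- fill(cfg$n_controls, function(g, cl) {
    u <- stats::runif(nrow(g))
    u >= p_a(g, cl) & stats::runif(nrow(g)) >= p_b(g, cl)
  })
  dos <- rbind(pa$g, pb$g, pc$g)
  covs <- rbind(pa$cov, pb$cov, pc$cov)
  n_tot <- nrow(dos)
  if (cfg$missing_rate > 0)
    dos[stats::runif(n_tot * m) < cfg$missing_rate] <- NA
  ids <- sprintf("S%05d", seq_len(n_tot))
  gm <- genotype_matrix(dos, panel$variants, ids)
  cohort <- cohort_table(data.frame(
    sample_id = ids,
    label = rep(c("case", "case", "control"),
                c(cfg$n_cases_a, cfg$n_cases_b, cfg$n_controls)),
    cohort = rep(c("A", "B", "control"),
                 c(cfg$n_cases_a, cfg$n_cases_b, cfg$n_controls)),
    covs, row.names = NULL, stringsAsFactors = FALSE))
  wt <- weight_table(panel$variants$vid, panel$variants$allele_b,
                     panel$variants$allele_a, beta_a, panel$source)
  list(genotypes = gm, cohort = cohort, weights = wt,
       truth = list(beta_a = beta_a, beta_b = beta_b,
                    alpha_a = alpha_a, alpha_b = alpha_b,
                    mafs = panel$mafs))
}

# straightforward double-loop scorer kept as an in-bundle reference,
# deliberately independent of the vectorized weighted_prs path
reference_scores <- function(gm, wt, mode = "average") {
  idx <- match(wt$vid, gm$variants$vid)
  stopifnot(!anyNA(idx))
  n <- nrow(gm$dosages)
  wprs <- numeric(n)
  p_hat <- vapply(idx, function(j)
    mean(gm$dosages[, j], na.rm = TRUE) / 2, numeric(1))
  for (i in seq_len(n)) {
    s <- 0; m_obs <- 0
    for (k in seq_along(idx)) {
      g <- gm$dosages[i, idx[k]]
      if (is.na(g)) g <- 2 * p_hat[k] else m_obs <- m_obs + 1
      s <- s + wt$weight[k] * g
    }
    wprs[i] <- if (mode == "sum") s else s / (2 * m_obs)
  }
  wprs
}

#' Write a reproducible end-to-end fixture bundle
#'
#' Simulates a full two-cohort study from `cfg` and writes: a PLINK
#' bed/bim/fam triplet, the same genotypes as VCF, the weight table TSV,
#' the cohort CSV, and an expected-results TSV holding per-sample scores
#' from an independent double-loop reference scorer plus the pooled
#' tertile group counts. A manifest of MD5 hashes makes regeneration
#' checkable.
#'
#' @param cfg a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @param seed seed (defaults to `cfg$seed`).
#' @return data.frame manifest (`file`, `md5`), invisibly; also written
#'   as `manifest.tsv`.
#' @export
make_fixture_bundle <- function(cfg, outdir, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_case_control(cfg, seed = seed)
  write_plink(sim$genotypes, file.path(outdir, "genotypes"))
  write_vcf(sim$genotypes, file.path(outdir, "genotypes.vcf"))
  write_weight_table(sim$weights, file.path(outdir, "weights.tsv"))
  write_cohort_table(sim$cohort, file.path(outdir, "cohort.csv"))

  wprs <- reference_scores(sim$genotypes, sim$weights, mode = "average")
  tert <- tertile_stratify(wprs, sim$genotypes$sample_ids,
                           pooling = "all simulated samples")
  expected <- data.frame(sample_id = sim$genotypes$sample_ids,
                         wprs = wprs, tertile = as.character(tert$group),
                         stringsAsFactors = FALSE)
  utils::write.table(expected, file.path(outdir, "expected_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- c("genotypes.bed", "genotypes.bim", "genotypes.fam",
             "genotypes.vcf", "weights.tsv", "cohort.csv",
             "expected_scores.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
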