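#' Per-variant genotyping call rate
#'
#' Fraction of samples with a non-missing genotype.
#'
#' @param gm a [genotype_matrix()].
#' @param vid a single variant id, or `NULL` for all variants.
#' @return Named numeric vector (or scalar for one `vid`).
#' @export
call_rate <- function(gm, vid = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cr <- colMeans(!is.na(gm$dosages))
  if (is.null(vid)) return(cr)
  if (!vid %in% names(cr)) stop("unknown vid: ", vid)
  cr[[vid]]
}

#' Minor allele frequency
#'
#' `min(p, 1 - p)` where `p` is the in-sample frequency of the counted
#' allele among non-missing genotypes.
#'
#' @inheritParams call_rate
#' @return Named numeric vector (or scalar for one `vid`).
#' @export
maf <- function(gm, vid = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p <- colMeans(gm$dosages, na.rm = TRUE) / 2
  if (any(is.nan(p)))
    stop("allele frequency undefined (all genotypes missing) for: ",
         paste(gm$variants$vid[is.nan(p)], collapse = ", "))
  out <- pmin(p, 1 - p)
  if (is.null(vid)) return(out)
  if (!vid %in% names(out)) stop("unknown vid: ", vid)
  out[[vid]]
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided conditional exact test (Wigginton-style): with the observed
#' allele counts fixed, the p-value sums the probabilities of every
#' heterozygote count whose conditional probability does not exceed that
#' of the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom, het, hom).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotype required")
  rare <- 2 * min(n_aa, n_bb) + n_ab          # minor allele count
  # support: het counts with the parity of `rare`, 0..rare (and <= 2n-rare)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  if (length(hets) == 1) return(1)
  # unnormalized log-probabilities of the conditional distribution
  lp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- n_ab
  p_obs <- pr[match(obs, hets)]
  if (is.na(p_obs)) stop("observed het count inconsistent with allele counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage vectors over jointly
#' non-missing samples.
#'
#' @param gm a [genotype_matrix()].
#' @param vid1,vid2 variant ids.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(gm, vid1, vid2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  i <- match(c(vid1, vid2), gm$variants$vid)
  if (anyNA(i)) stop("unknown vid(s)")
  x <- gm$dosages[, i[1]]; y <- gm$dosages[, i[2]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("r2 undefined: variant monomorphic in the joint sample (",
         vid1, ", ", vid2, ")")
  stats::cor(x[ok], y[ok])^2
}

#' Variant QC thresholds
#'
#' Defaults follow common array-QC practice: call rate >= 95%,
#' MAF >= 1%, HWE exact p >= 1e-6, and pairwise LD r2 < 0.8 for pruning.
#'
#' @param min_call_rate,min_maf,min_hwe_p,max_ld_r2 fractions in \[0, 1\].
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.01,
                          min_hwe_p = 1e-6, max_ld_r2 = 0.8) {
  v <- c(min_call_rate, min_maf, min_hwe_p, max_ld_r2)
  if (any(v < 0 | v > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p, max_ld_r2 = max_ld_r2),
            class = "qc_thresholds")
}

hwe_p_by_variant <- function(gm) {
  apply(gm$dosages, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
  })
}

#' Apply variant quality-control filters
#'
#' Keeps variants passing call rate, MAF and HWE thresholds. The report
#' lists every variant's metrics and, for failures, the first failing
#' rule (checked in the order call rate, MAF, HWE).
#'
#' @param gm a [genotype_matrix()].
#' @param thr a [qc_thresholds()].
#' @param hwe_samples `"all"` (default) or `"controls"`; the latter
#'   evaluates HWE in control samples only.
#' @param cohort a [cohort_table()]; required when
#'   `hwe_samples = "controls"`.
#' @return List with `genotypes` (filtered matrix) and `report`
#'   (data.frame: `vid`, `call_rate`, `maf`, `hwe_p`, `pass`,
#'   `fail_reason`).
#' @export
apply_qc <- function(gm, thr = qc_thresholds(),
                     hwe_samples = c("all", "controls"), cohort = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(thr, "qc_thresholds"))
  hwe_samples <- match.arg(hwe_samples)
  cr <- call_rate(gm)
  fr <- maf(gm)
  hgm <- gm
  if (hwe_samples == "controls") {
    if (is.null(cohort)) stop("cohort table required for controls-only HWE")
    ctrl <- cohort$sample_id[cohort$label == "control"]
    hgm <- subset_genotypes(gm, sample_ids = intersect(gm$sample_ids, ctrl))
  }
  hp <- hwe_p_by_variant(hgm)

  fail_reason <- rep("", ncol(gm$dosages))
  fail_reason[cr < thr$min_call_rate] <- "call_rate"
  fail_reason[fail_reason == "" & fr < thr$min_maf] <- "maf"
  fail_reason[fail_reason == "" & (is.na(hp) | hp < thr$min_hwe_p)] <- "hwe"
  pass <- fail_reason == ""

  report <- data.frame(vid = gm$variants$vid, call_rate = cr, maf = fr,
                       hwe_p = hp, pass = pass, fail_reason = fail_reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!any(pass)) {
    warning("no variants pass QC")
    kept <- gm
    kept$dosages <- gm$dosages[, 0, drop = FALSE]
    kept$variants <- gm$variants[0, , drop = FALSE]
  } else {
    kept <- subset_genotypes(gm, vids = gm$variants$vid[pass])
  }
  list(genotypes = kept, report = report)
}

#' Greedy LD pruning
#'
#' Scans variants in input (genomic) order; a variant is dropped when its
#' r-squared with any previously kept variant on the same chromosome
#' exceeds `max_r2`. Variants for which r2 is undefined against a kept
#' variant (monomorphic in the joint sample) are dropped with a warning.
#'
#' @param gm a [genotype_matrix()], variants sorted by (chrom, pos).
#' @param max_r2 retain pairs with r-squared at or below this bound.
#' @return Character vector of kept variant ids.
#' @export
ld_prune <- function(gm, max_r2 = 0.8) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  kept <- character(0)
  kept_chrom <- character(0)
  dropped_undef <- character(0)
  for (k in seq_len(nrow(v))) {
    same <- kept[kept_chrom == v$chrom[k]]
    ok <- TRUE
    for (u in same) {
      r2 <- tryCatch(ld_r2(gm, u, v$vid[k]), error = function(e) NA_real_)
      if (is.na(r2)) {
        dropped_undef <- c(dropped_undef, v$vid[k]); ok <- FALSE; break
      }
      if (r2 > max_r2) { ok <- FALSE; break }
    }
    if (ok) { kept <- c(kept, v$vid[k]); kept_chrom <- c(kept_chrom, v$chrom[k]) }
  }
  if (length(dropped_undef))
    warning("dropped variant(s) with undefined r2: ",
            paste(unique(dropped_undef), collapse = ", "))
  kept
}

#' Genotype principal components
#'
#' PCA of the column-standardized dosage matrix (missing cells
#' mean-imputed first), for use as ancestry covariates. The sign of each
#' component is fixed so that its largest-magnitude variant loading is
#' positive.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components, `0 <= k <= min(n_samples, n_variants)`.
#' @return `n_samples x k` score matrix (columns `PC1..PCk`), with the
#'   variant loadings in attribute `"rotation"`.
#' @export
genotype_pca <- function(gm, k = 4) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (k < 0 || k > min(dim(gm$dosages)))
    stop("k must lie in [0, min(n_samples, n_variants)]")
  if (k == 0)
    return(matrix(numeric(0), nrow(gm$dosages), 0,
                  dimnames = list(gm$sample_ids, NULL)))
  x <- mean_impute(gm)$dosages
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all variants have zero variance; PCA undefined")
  x <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(k))
  rownames(scores) <- gm$sample_ids
  attr(scores, "rotation") <- rot
  scores
}
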