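#' Orient weights so every effect allele is the risk allele
#'
#' Variants with a negative log-odds weight are re-oriented: effect and
#' other alleles are swapped and the weight negated. Afterwards all
#' weights are non-negative and the effect allele of every variant is the
#' risk allele, which makes the summed risk-allele count well-defined.
#'
#' @param wt a [weight_table()].
#' @return A `weight_table` with non-negative weights.
#' @export
orient_weights <- function(wt) {
  stopifnot(inherits(wt, "weight_table"))
  neg <- wt$weight < 0
  if (any(neg)) {
    tmp <- wt$effect_allele[neg]
    wt$effect_allele[neg] <- wt$other_allele[neg]
    wt$other_allele[neg] <- tmp
    wt$weight[neg] <- -wt$weight[neg]
  }
  wt
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing cell with `2 * p_hat`, the expected dosage under
#' the in-sample frequency `p_hat` of the counted allele at that variant.
#' Observed cells are unchanged.
#'
#' @param gm a [genotype_matrix()]; every variant needs at least one
#'   observed genotype.
#' @return A `genotype_matrix` with real-valued dosages and no missing
#'   cells; the number of imputed cells per sample is kept in attribute
#'   `"n_imputed"` of the dosage matrix.
#' @export
mean_impute <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  miss <- is.na(d)
  if (!any(miss)) {
    attr(gm$dosages, "n_imputed") <- integer(nrow(d))
    return(gm)
  }
  mu <- colMeans(d, na.rm = TRUE)
  if (any(is.nan(mu)))
    stop("cannot impute fully missing variant(s): ",
         paste(gm$variants$vid[is.nan(mu)], collapse = ", "))
  idx <- which(miss, arr.ind = TRUE)
  d[miss] <- mu[idx[, 2]]
  out <- genotype_matrix(d, gm$variants, gm$sample_ids, allow_real = TRUE)
  attr(out$dosages, "n_imputed") <- as.integer(rowSums(miss))
  out
}

#' Weighted polygenic risk score
#'
#' Additive score over a harmonized variant panel. In `sum` mode
#' `wprs_i = sum_j beta_j * g_ij` after mean imputation of missing cells;
#' in `average` mode (the default, compatible with the usual per-allele
#' scoring convention) the same weighted sum is divided by `2 * M_i`,
#' where `M_i` counts the variants observed (non-missing before
#' imputation) for sample i.
#'
#' The genotype matrix must already be harmonized to the weight table
#' (see [harmonize()]) so that each dosage counts the effect allele.
#' Weights are applied as given; use [orient_weights()] first if the
#' risk-allele count should track positively weighted alleles.
#'
#' @param gm a harmonized [genotype_matrix()].
#' @param wt a [weight_table()]; variants absent from `gm` are excluded
#'   with a warning.
#' @param mode `"average"` or `"sum"`.
#' @return A data.frame of class `score_vector`: `sample_id`, `wprs`,
#'   `risk_allele_count` (observed dosage sum, missing cells contributing
#'   0), `n_used_variants`, `n_imputed_cells`, `mode`.
#' @export
weighted_prs <- function(gm, wt, mode = c("average", "sum")) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(wt, "weight_table"))
  mode <- match.arg(mode)
  idx <- match(wt$vid, gm$variants$vid)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " weight-table variant(s) absent from genotypes: ",
            paste(wt$vid[is.na(idx)], collapse = ", "))
    wt <- wt[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (!length(idx)) stop("no usable variants: weight table and genotypes are disjoint")
  mismatch <- gm$variants$allele_b[idx] != wt$effect_allele
  if (any(mismatch))
    stop("genotypes not harmonized to the weight table at: ",
         paste(wt$vid[mismatch], collapse = ", "))

  sub <- subset_genotypes(gm, vids = wt$vid)
  raw <- sub$dosages
  miss <- is.na(raw)
  m_obs <- ncol(raw) - rowSums(miss)
  if (any(m_obs == 0))
    stop("sample(s) with no observed genotypes across the panel")
  imp <- mean_impute(sub)$dosages
  num <- drop(imp %*% wt$weight)
  wprs <- switch(mode, sum = num, average = num / (2 * m_obs))

  rac <- as.integer(rowSums(raw, na.rm = TRUE))
  out <- data.frame(sample_id = gm$sample_ids, wprs = wprs,
                    risk_allele_count = rac,
                    n_used_variants = ncol(raw),
                    n_imputed_cells = as.integer(rowSums(miss)),
                    mode = mode, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Summed risk-allele count
#'
#' Integer count of risk alleles carried by each sample across the panel,
#' with missing cells contributing 0 (their number is reported).
#' Requires dosages harmonized so each counts the risk allele.
#'
#' @param gm a harmonized [genotype_matrix()] with hard calls.
#' @param wt a [weight_table()] oriented so effect allele = risk allele.
#' @return data.frame: `sample_id`, `risk_allele_count`,
#'   `n_used_variants`, `n_imputed_cells`.
#' @export
summed_risk_alleles <- function(gm, wt) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(wt, "weight_table"))
  if (any(wt$weight < 0))
    stop("weight table must be oriented (no negative weights); see orient_weights()")
  idx <- match(wt$vid, gm$variants$vid)
  wt <- wt[!is.na(idx), , drop = FALSE]
  if (!nrow(wt)) stop("no usable variants")
  sub <- subset_genotypes(gm, vids = wt$vid)
  miss <- is.na(sub$dosages)
  data.frame(sample_id = gm$sample_ids,
             risk_allele_count = as.integer(rowSums(sub$dosages, na.rm = TRUE)),
             n_used_variants = ncol(sub$dosages),
             n_imputed_cells = as.integer(rowSums(miss)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write per-sample scores as TSV
#'
#' @param scores a `score_vector` from [weighted_prs()].
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
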