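#' Genotype matrix container
#'
#' Holds a samples-by-variants matrix of additive allele dosages together
#' with variant and sample metadata. Dosages count copies of `allele_b`
#' (the "counted" allele) and are 0, 1, 2 or `NA` for a missing genotype.
#' After [mean_impute()] dosages may be real-valued in \[0, 2\].
#'
#' @param dosages numeric matrix, `n_samples x n_variants`; entries in
#'   `{0, 1, 2, NA}` unless `allow_real = TRUE`.
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `vid` (unique variant identifier), `allele_a`, `allele_b` (uppercase,
#'   non-empty, unequal). `allele_b` is the allele the dosages count.
#' @param sample_ids character vector of unique sample identifiers.
#' @param allow_real allow non-integer dosages (post-imputation matrices).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids,
                            allow_real = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  req <- c("chrom", "pos", "vid", "allele_a", "allele_b")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  variants <- as.data.frame(variants)[, req]
  variants$vid <- as.character(variants$vid)
  variants$chrom <- as.character(variants$chrom)
  variants$allele_a <- toupper(as.character(variants$allele_a))
  variants$allele_b <- toupper(as.character(variants$allele_b))
  sample_ids <- as.character(sample_ids)

  if (nrow(dosages) != length(sample_ids))
    stop("nrow(dosages) != length(sample_ids)")
  if (ncol(dosages) != nrow(variants))
    stop("ncol(dosages) != nrow(variants)")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(variants$vid)) stop("variant vids must be unique")
  if (any(variants$allele_a == variants$allele_b))
    stop("allele_a and allele_b must differ for every variant")
  if (any(variants$allele_a == "" | variants$allele_b == ""))
    stop("alleles must be non-empty")
  if (any(variants$pos < 1)) stop("positions are 1-based: pos >= 1")
  obs <- dosages[!is.na(dosages)]
  if (any(obs < 0 | obs > 2))
    stop("dosages must lie in [0, 2]")
  if (!allow_real && !all(obs %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or NA (use allow_real = TRUE for imputed matrices)")

  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$vid
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by variant id and/or sample id
#'
#' @param gm a [genotype_matrix()].
#' @param vids variant ids to keep (in the given order); `NULL` keeps all.
#' @param sample_ids sample ids to keep; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the requested entries.
#' @export
subset_genotypes <- function(gm, vids = NULL, sample_ids = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  vi <- if (is.null(vids)) seq_len(ncol(gm$dosages)) else {
    idx <- match(vids, gm$variants$vid)
    if (anyNA(idx)) stop("unknown vid(s): ",
                         paste(vids[is.na(idx)], collapse = ", "))
    idx
  }
  si <- if (is.null(sample_ids)) seq_len(nrow(gm$dosages)) else {
    idx <- match(sample_ids, gm$sample_ids)
    if (anyNA(idx)) stop("unknown sample id(s)")
    idx
  }
  genotype_matrix(gm$dosages[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE],
                  gm$sample_ids[si], allow_real = TRUE)
}

#' Variant weight table
#'
#' Per-variant effect allele and additive log-odds weight, the beta_j of a
#' weighted polygenic risk score. Weights are natural-log odds ratios from
#' association studies.
#'
#' @param vid unique variant identifiers.
#' @param effect_allele allele whose dosage multiplies the weight.
#' @param other_allele the second allele.
#' @param weight finite numeric log-odds weights.
#' @param source optional per-variant tag (e.g. `"gwas"` or `"reported"`).
#' @return A data.frame of class `weight_table`.
#' @export
weight_table <- function(vid, effect_allele, other_allele, weight,
                         source = "gwas") {
  wt <- data.frame(vid = as.character(vid),
                   effect_allele = toupper(as.character(effect_allele)),
                   other_allele = toupper(as.character(other_allele)),
                   weight = as.numeric(weight),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(wt$vid)) stop("weight table vids must be unique")
  if (any(!is.finite(wt$weight))) stop("weights must be finite")
  if (any(wt$effect_allele == wt$other_allele))
    stop("effect_allele must differ from other_allele")
  class(wt) <- c("weight_table", "data.frame")
  wt
}

#' Cohort phenotype and covariate table
#'
#' Per-sample case/control label, cohort tag and adjustment covariates
#' (age in years; sex and four binary risk-factor flags; optionally
#' genotype principal components).
#'
#' @param df data.frame with at least `sample_id`, `label`
#'   (`"case"`/`"control"`) and `cohort`.
#' @return The data.frame with class `cohort_table` prepended.
#' @export
cohort_table <- function(df) {
  req <- c("sample_id", "label", "cohort")
  if (!all(req %in% names(df)))
    stop("cohort table needs columns: ", paste(req, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$label <- as.character(df$label)
  df$cohort <- as.character(df$cohort)
  if (anyNA(df$label) || !all(df$label %in% c("case", "control")))
    stop("label must be 'case' or 'control' with no missing values")
  if (anyDuplicated(df$sample_id)) stop("sample_id must be unique")
  class(df) <- unique(c("cohort_table", class(df)))
  df
}
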