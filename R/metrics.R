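as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  l <- as.character(labels)
  if (!all(l %in% c("case", "control")))
    stop("labels must be logical, 0/1, or 'case'/'control'")
  l == "case"
}

roc_summary <- function(auroc, ci, n_cases, n_controls, method) {
  structure(list(auroc = auroc, ci_low = ci[1], ci_high = ci[2],
                 n_cases = n_cases, n_controls = n_controls,
                 method = method),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUROC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls [%s]\n",
              x$auroc, x$ci_low, x$ci_high, x$n_cases, x$n_controls,
              x$method))
  invisible(x)
}

#' Nonparametric AUROC
#'
#' Tie-corrected Mann-Whitney estimate: the probability that a random
#' case outscores a random control, with half credit for ties. The 95%
#' confidence interval uses the DeLong structural-components variance.
#'
#' @param labels case/control labels (logical, 0/1, or
#'   `"case"`/`"control"`); `TRUE`/1/case is the positive class.
#' @param scores numeric scores, higher = more case-like.
#' @return A `roc_summary`: `auroc`, `ci_low`, `ci_high`, `n_cases`,
#'   `n_controls`, `method`.
#' @export
auroc <- function(labels, scores) {
  case <- as_case_logical(labels)
  stopifnot(length(case) == length(scores))
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # midranks handle ties
  a <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  roc_summary(a, delong_ci(case, scores), n1, n0, "continuous")
}

#' DeLong confidence interval for the AUROC
#'
#' Normal-approximation interval from the DeLong structural-components
#' variance, truncated to \[0, 1\]. A degenerate variance (e.g. AUROC
#' exactly 0 or 1) yields a one-sided collapsed interval with a warning.
#'
#' @inheritParams auroc
#' @param alpha two-sided error level (default 0.05).
#' @return `c(low, high)`.
#' @export
delong_ci <- function(labels, scores, alpha = 0.05) {
  case <- as_case_logical(labels)
  x <- scores[case]; y <- scores[!case]
  n1 <- length(x); n0 <- length(y)
  if (n1 < 1 || n0 < 1) stop("both classes must be present")
  # structural components: V10_i = P(case_i beats a control), V01_j likewise
  v10 <- vapply(x, function(s) (sum(s > y) + 0.5 * sum(s == y)) / n0,
                numeric(1))
  v01 <- vapply(y, function(s) (sum(x > s) + 0.5 * sum(x == s)) / n1,
                numeric(1))
  a <- mean(v10)
  s2 <- (if (n1 > 1) stats::var(v10) / n1 else 0) +
    (if (n0 > 1) stats::var(v01) / n0 else 0)
  if (s2 <= 0) {
    warning("degenerate DeLong variance; interval collapsed at the estimate")
    return(c(max(0, a), min(1, a)))
  }
  z <- stats::qnorm(1 - alpha / 2)
  c(max(0, a - z * sqrt(s2)), min(1, a + z * sqrt(s2)))
}

expand_ordinal <- function(case_counts, control_counts) {
  k <- length(case_counts)
  if (length(control_counts) != k || k < 1)
    stop("case and control counts must have the same number of levels")
  if (any(case_counts < 0) || any(control_counts < 0))
    stop("counts must be non-negative")
  if (sum(case_counts) == 0 || sum(control_counts) == 0)
    stop("both classes must have positive totals")
  lev <- seq_len(k)
  list(scores = c(rep(lev, case_counts), rep(lev, control_counts)),
       case = c(rep(TRUE, sum(case_counts)), rep(FALSE, sum(control_counts))))
}

#' AUROC of an ordinal (grouped) classifier
#'
#' Applies the same tie-corrected pair counting as [auroc()] to data
#' grouped into ordered risk levels (e.g. tertiles), with a DeLong CI.
#' This is the statistic a tabulated ROC routine reports for a K-level
#' risk table.
#'
#' @param case_counts,control_counts per-level counts, lowest risk level
#'   first; equal length `K >= 1`.
#' @return A `roc_summary` with `method = "ordinal"`.
#' @export
auroc_from_ordinal <- function(case_counts, control_counts) {
  e <- expand_ordinal(case_counts, control_counts)
  if (length(case_counts) == 1)
    return(roc_summary(0.5, c(0.5, 0.5), sum(case_counts),
                       sum(control_counts), "ordinal"))
  out <- auroc(e$case, e$scores)
  out$method <- "ordinal"
  out
}

#' Sensitivity, specificity and accuracy at an ordinal threshold
#'
#' Predicts "case" for samples at or above `threshold_level`.
#'
#' @inheritParams auroc_from_ordinal
#' @param threshold_level level index in `1..K`.
#' @return Named list: `sensitivity` (cases at/above threshold / cases),
#'   `specificity` (controls below threshold / controls), `accuracy`
#'   (correct calls / total).
#' @export
threshold_metrics <- function(case_counts, control_counts, threshold_level) {
  k <- length(case_counts)
  if (length(control_counts) != k)
    stop("case and control counts must have the same number of levels")
  if (threshold_level < 1 || threshold_level > k)
    stop("threshold_level outside 1..", k)
  n1 <- sum(case_counts); n0 <- sum(control_counts)
  at_above <- seq_len(k) >= threshold_level
  sens <- sum(case_counts[at_above]) / n1
  spec <- sum(control_counts[!at_above]) / n0
  acc <- (sum(case_counts[at_above]) + sum(control_counts[!at_above])) /
    (n1 + n0)
  list(sensitivity = sens, specificity = spec, accuracy = acc)
}
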