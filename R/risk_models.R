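#' Tertile stratification of pooled scores
#'
#' Splits scores at the empirical 1/3 and 2/3 quantiles of the pooled
#' score vector into low (T1), middle (T2) and high (T3) risk groups.
#' Boundaries use a nearest-rank convention: the order statistics at
#' ranks `floor(n/3) + 1` and `floor(2n/3) + 1`. Assignment: score below
#' the lower boundary is T1, in \[lower, upper) is T2, at or above the
#' upper boundary is T3 — ties at a boundary go to the upper group. With
#' distinct scores the three groups differ in size by at most 2 (exactly
#' n/3 each when 3 divides n).
#'
#' @param scores numeric vector of pooled scores (e.g. both case cohorts
#'   plus the shared controls), all finite, length >= 3.
#' @param sample_ids optional ids (defaults to `names(scores)` or an
#'   index).
#' @param pooling description of which samples defined the boundaries.
#' @return A list of class `tertile_assignment`: `boundaries`
#'   (`c(lower, upper)`), `group` (factor `T1/T2/T3` named by sample id),
#'   `pooling`.
#' @export
tertile_stratify <- function(scores, sample_ids = NULL,
                             pooling = "all pooled samples") {
  if (length(scores) < 3) stop("need at least 3 samples")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(scores)) == 1)
    stop("degenerate stratification: all scores identical")
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(names(scores))) names(scores)
      else as.character(seq_along(scores))
  n <- length(scores)
  s <- sort(scores)
  b <- c(s[floor(n / 3) + 1], s[floor(2 * n / 3) + 1])
  group <- factor(ifelse(scores < b[1], "T1",
                         ifelse(scores < b[2], "T2", "T3")),
                  levels = c("T1", "T2", "T3"))
  names(group) <- sample_ids
  structure(list(boundaries = b, group = group, pooling = pooling),
            class = "tertile_assignment")
}

#' @export
print.tertile_assignment <- function(x, ...) {
  cat(sprintf("tertiles at %.4g / %.4g (%s): %s\n",
              x$boundaries[1], x$boundaries[2], x$pooling,
              paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

firth_fit <- function(X, y, max_iter = 100, tol = 1e-8) {
  # Jeffreys-prior penalized likelihood (bias-reduced) logistic fit
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    h <- diag(XW %*% solve(info, t(XW)))
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- solve(info, U)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  list(coef = b, vcov = solve(info), converged = max(abs(step)) < tol)
}

#' Maximum-likelihood logistic regression fit
#'
#' IRLS fit via [stats::glm()] with Wald 95% confidence intervals
#' `exp(b +/- 1.96 se)`. Quasi-complete separation (detected by huge
#' standard errors or non-convergence) is flagged, and can trigger a
#' Firth-type bias-reduced refit.
#'
#' @param y binary outcome (0/1, logical, or case/control labels).
#' @param X numeric design matrix; an intercept column is prepended when
#'   no constant column is present.
#' @param firth `"never"`, `"on_separation"` (refit only when separation
#'   or non-convergence is detected) or `"always"`.
#' @param conf_level confidence level for the Wald intervals.
#' @return A list of class `logistic_fit`: `coef`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p` (Wald), `converged`, `separation`, `method`,
#'   `n_cases`, `n_controls`.
#' @export
fit_logistic <- function(y, X, firth = c("on_separation", "never", "always"),
                         conf_level = 0.95) {
  firth <- match.arg(firth)
  y <- as.numeric(as_case_logical(y))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0)))
    X <- cbind(`(Intercept)` = 1, X)
  if (length(y) <= ncol(X)) stop("more parameters than observations")
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")

  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 100)))
  b <- fit$coefficients
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  V <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(V)) rep(Inf, length(b)) else sqrt(diag(V))
  separation <- !fit$converged || any(!is.finite(se)) || any(se > 10) ||
    any(abs(b[-1]) > 15)
  method <- "ml"
  converged <- fit$converged

  if (firth == "always" || (firth == "on_separation" && separation)) {
    if (separation && firth == "on_separation")
      warning("separation detected; reporting Firth bias-reduced fit")
    ff <- firth_fit(X, y)
    b <- ff$coef
    se <- sqrt(diag(ff$vcov))
    converged <- ff$converged
    method <- "firth"
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  names(b) <- names(se) <- colnames(X)
  structure(list(coef = b, se = se, or = exp(b),
                 ci_low = exp(b - z * se), ci_high = exp(b + z * se),
                 p = 2 * stats::pnorm(-abs(b / se)),
                 converged = converged, separation = separation,
                 method = method,
                 n_cases = sum(y == 1), n_controls = sum(y == 0)),
            class = "logistic_fit")
}

#' Per-tertile risk table for each case cohort against shared controls
#'
#' Builds, per case cohort, the standard tertile risk table: case and
#' control counts with percentages, odds ratios versus the lowest tertile
#' from a logistic model with tertile indicators plus any adjustment
#' covariates, cumulative sensitivity/specificity at each tertile
#' threshold, and the ordinal AUROC of the tertile classifier.
#'
#' @param assignment a [tertile_stratify()] result covering all samples.
#' @param cohort a [cohort_table()]; controls are the samples with
#'   `label == "control"` and are shared across case cohorts.
#' @param adjust character vector of cohort-table covariate columns to
#'   adjust for (empty = unadjusted ORs).
#' @param firth separation policy passed to [fit_logistic()].
#' @return A data.frame of class `risk_table`, one row per cohort x
#'   tertile: `cohort`, `tertile`, `range`, `case_n`, `case_pct`,
#'   `control_n`, `control_pct`, `or`, `ci_low`, `ci_high`, `p`,
#'   `sensitivity`, `specificity`, `auroc` (on the T3 row). The
#'   `roc_summary` objects are kept in attribute `"roc"`.
#' @export
tertile_risk_table <- function(assignment, cohort, adjust = character(),
                               firth = "on_separation") {
  stopifnot(inherits(assignment, "tertile_assignment"),
            inherits(cohort, "cohort_table"))
  miss <- setdiff(cohort$sample_id, names(assignment$group))
  if (length(miss))
    stop("samples missing from tertile assignment: ",
         paste(utils::head(miss, 5), collapse = ", "))
  bad <- setdiff(adjust, names(cohort))
  if (length(bad))
    stop("unknown adjustment covariate(s): ", paste(bad, collapse = ", "))

  grp <- assignment$group[cohort$sample_id]
  b <- assignment$boundaries
  ranges <- c(sprintf("<%.3f", b[1]),
              sprintf("%.3f-%.3f", b[1], b[2]),
              sprintf(">=%.3f", b[2]))
  ctrl <- cohort$label == "control"
  if (!any(ctrl)) stop("no control samples")
  control_counts <- as.vector(table(grp[ctrl]))
  case_tags <- unique(cohort$cohort[!ctrl])

  rows <- list()
  rocs <- list()
  for (tag in case_tags) {
    sel <- ctrl | (cohort$cohort == tag & !ctrl)
    sub <- cohort[sel, , drop = FALSE]
    g <- grp[sel]
    y <- sub$label == "case"
    case_counts <- as.vector(table(g[y]))
    if (case_counts[1] == 0 || control_counts[1] == 0)
      stop("empty reference tertile (T1) in cohort ", tag,
           ": odds ratios undefined")

    X <- cbind(T2 = as.numeric(g == "T2"), T3 = as.numeric(g == "T3"))
    if (length(adjust))
      X <- cbind(X, as.matrix(
        data.matrix(sub[, adjust, drop = FALSE])))
    fit <- fit_logistic(y, X, firth = firth)

    roc <- auroc_from_ordinal(case_counts, control_counts)
    rocs[[tag]] <- roc
    tm2 <- threshold_metrics(case_counts, control_counts, 2)
    tm3 <- threshold_metrics(case_counts, control_counts, 3)

    rows[[tag]] <- data.frame(
      cohort = tag, tertile = c("T1", "T2", "T3"), range = ranges,
      case_n = case_counts,
      case_pct = round(100 * case_counts / sum(case_counts), 1),
      control_n = control_counts,
      control_pct = round(100 * control_counts / sum(control_counts), 1),
      or = c(1, fit$or[c("T2", "T3")]),
      ci_low = c(NA, fit$ci_low[c("T2", "T3")]),
      ci_high = c(NA, fit$ci_high[c("T2", "T3")]),
      p = c(NA, fit$p[c("T2", "T3")]),
      sensitivity = c(NA, tm2$sensitivity, tm3$sensitivity),
      specificity = c(NA, tm2$specificity, tm3$specificity),
      auroc = c(NA, NA, roc$auroc),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "roc") <- rocs
  class(out) <- c("risk_table", "data.frame")
  out
}

#' Write a risk table as TSV
#'
#' @param rt a [tertile_risk_table()] result.
#' @param path output file.
#' @export
write_risk_table <- function(rt, path) {
  utils::write.table(as.data.frame(rt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
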