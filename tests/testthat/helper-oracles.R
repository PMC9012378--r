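# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's vectorized code paths.

# minimal byte-level PLINK bed decoder: per-sample bit arithmetic, no
# shared code with read_plink
oracle_read_bed <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), colClasses = "character")
  fam <- read.table(paste0(prefix, ".fam"), colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- as.integer(readBin(paste0(prefix, ".bed"), "raw",
                            n = 3 + m * ceiling(n / 4)))
  stopifnot(raw[1] == 108, raw[2] == 27, raw[3] == 1)
  body <- raw[-(1:3)]
  bpv <- ceiling(n / 4)
  out <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      byte <- body[(j - 1) * bpv + (i - 1) %/% 4 + 1]
      code <- (byte %/% 4^((i - 1) %% 4)) %% 4
      out[i, j] <- switch(code + 1, 2, NA_real_, 1, 0)
    }
  }
  out
}

# HWE exact test by full enumeration of the conditional distribution:
# P(n_ab) proportional to  multinomial(n; n_aa, n_ab, n_bb) * 2^n_ab
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab           # allele-a count
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  lp <- sapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2)
  })
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  p_obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# AUROC by exhaustive case-control pair counting
oracle_auc <- function(case, scores) {
  x <- scores[case]; y <- scores[!case]
  s <- 0
  for (xi in x) for (yj in y)
    s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# naive double-loop weighted PRS with in-sample mean imputation
oracle_prs <- function(gm, wt, mode) {
  idx <- match(wt$vid, gm$variants$vid)
  n <- nrow(gm$dosages)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0; m_obs <- 0
    for (k in seq_along(idx)) {
      g <- gm$dosages[i, idx[k]]
      if (is.na(g)) {
        g <- mean(gm$dosages[, idx[k]], na.rm = TRUE)
      } else m_obs <- m_obs + 1
      s <- s + wt$weight[k] * g
    }
    out[i] <- if (mode == "sum") s else s / (2 * m_obs)
  }
  out
}

# random hard-call genotype matrix with non-palindromic alleles
random_gm <- function(n, m, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  al <- pairs[sample(4, m, replace = TRUE), , drop = FALSE]
  mafs <- runif(m, 0.1, 0.5)
  dos <- matrix(rbinom(n * m, 2, rep(mafs, each = n)), n, m)
  if (missing_rate > 0) dos[runif(n * m) < missing_rate] <- NA
  genotype_matrix(dos,
                  data.frame(chrom = as.character(rep(1, m)),
                             pos = seq_len(m) * 100L,
                             vid = sprintf("v%03d", seq_len(m)),
                             allele_a = al[, 1], allele_b = al[, 2],
                             stringsAsFactors = FALSE),
                  sprintf("s%03d", seq_len(n)))
}

random_wt <- function(gm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  weight_table(gm$variants$vid, gm$variants$allele_b,
               gm$variants$allele_a, rnorm(ncol(gm$dosages), 0.3, 0.3))
}
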