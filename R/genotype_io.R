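#' Read a PLINK 1.x bed/bim/fam fileset
#'
#' Reads a SNP-major binary fileset into a [genotype_matrix()]. Dosages
#' count the bim file's first-listed allele (A1), which is stored as
#' `allele_b` (the counted allele); A2 becomes `allele_a`. Missing
#' genotypes (2-bit code `01`) become `NA`.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @return A `genotype_matrix` with variants in bim order.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths)
    if (!file.exists(p)) stop("missing PLINK file: ", p)

  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 2) stop("malformed fam file: ", paths[3])
  sample_ids <- fam[[2]]

  bim <- utils::read.table(paths[2], header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer",
                                          "character", "character"))
  if (ncol(bim) != 6) stop("malformed bim file: ", paths[2])
  variants <- data.frame(chrom = bim[[1]], pos = bim[[4]], vid = bim[[2]],
                         allele_a = toupper(bim[[6]]),   # A2
                         allele_b = toupper(bim[[5]]),   # A1, counted
                         stringsAsFactors = FALSE)

  n <- length(sample_ids)
  m <- nrow(variants)
  bpv <- ceiling(n / 4)                 # bytes per variant, SNP-major
  raw <- readBin(paths[1], "raw", n = 3 + m * bpv)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed magic bytes in bed file: ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop("bed file is not SNP-major: ", paths[1])
  if (length(raw) < 3 + m * bpv)
    stop("bed file truncated: ", paths[1], " (expected ",
         3 + m * bpv, " bytes, got ", length(raw), ")")

  body <- as.integer(raw[-(1:3)])
  dim(body) <- c(bpv, m)
  # unpack 2-bit codes: sample i sits in byte (i-1)%/%4 + 1, bits 2*((i-1)%%4)
  dos <- matrix(NA_real_, n, m)
  code_map <- c(2, NA, 1, 0)            # 00->2 A1, 01->missing, 10->het, 11->0
  for (slot in 0:3) {
    idx <- seq(slot + 1, n, by = 4)
    if (!length(idx)) next
    rows <- (idx - 1) %/% 4 + 1
    codes <- bitwAnd(bitwShiftR(body[rows, , drop = FALSE], 2L * slot), 3L)
    dos[idx, ] <- code_map[codes + 1L]
  }
  genotype_matrix(dos, variants, sample_ids)
}

#' Write a PLINK 1.x bed/bim/fam fileset
#'
#' Inverse of [read_plink()]: `allele_b` is written as A1 (so dosages
#' count A1) and `allele_a` as A2. Dosages must be integer 0/1/2/NA.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  if (!all(d[!is.na(d)] %in% c(0, 1, 2)))
    stop("write_plink requires hard-call dosages 0/1/2/NA")
  v <- gm$variants
  utils::write.table(
    data.frame(v$chrom, v$vid, 0L, v$pos, v$allele_b, v$allele_a),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(gm$sample_ids, gm$sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  n <- nrow(d); m <- ncol(d); bpv <- ceiling(n / 4)
  # dosage -> 2-bit code: 2->00, NA->01, 1->10, 0->11
  code <- matrix(3L, n, m)
  code[d == 2] <- 0L
  code[d == 1] <- 2L
  code[is.na(d)] <- 1L
  padded <- matrix(0L, bpv * 4, m)
  padded[seq_len(n), ] <- code
  dim(padded) <- c(4, bpv * m)
  bytes <- padded[1, ] + bitwShiftL(padded[2, ], 2L) +
    bitwShiftL(padded[3, ], 4L) + bitwShiftL(padded[4, ], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read a VCF into a genotype matrix
#'
#' Parses diploid GT calls: dosage = number of ALT alleles, `./.` becomes
#' `NA`. REF is stored as `allele_a`, ALT as `allele_b` (the counted
#' allele). Multi-allelic records are rejected.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return A `genotype_matrix` with variants in file order.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("missing VCF file: ", path)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic VCF record(s) not supported: record ",
         paste(which(multi), collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")   # variants x samples
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  sample_ids <- colnames(gt)

  vid <- fix[, "ID"]
  noid <- is.na(vid) | vid == "."
  vid[noid] <- paste(fix[noid, "CHROM"], fix[noid, "POS"],
                     fix[noid, "REF"], fix[noid, "ALT"], sep = ":")
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         vid = vid,
                         allele_a = toupper(fix[, "REF"]),
                         allele_b = toupper(fix[, "ALT"]),
                         stringsAsFactors = FALSE)

  bad_ploidy <- !is.na(gt) & !grepl("^[.01]([/|][.01])?$", gt)
  bad_ploidy <- bad_ploidy | (!is.na(gt) & !grepl("[/|]", gt))
  if (any(bad_ploidy)) {
    w <- which(bad_ploidy, arr.ind = TRUE)[1, ]
    stop("non-diploid or malformed GT '", gt[w[1], w[2]],
         "' at record ", w[1], " (", variants$vid[w[1]], ")")
  }
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    ok <- !is.na(g) & !grepl(".", g, fixed = TRUE)
    out[ok] <- vapply(strsplit(g[ok], "[/|]"),
                      function(a) sum(a == "1"), numeric(1))
    out
  }
  dos <- apply(gt, 1, count_alt)                # samples x variants
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = length(sample_ids))
  genotype_matrix(dos, variants, sample_ids)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' `allele_a` is written as REF and `allele_b` as ALT, so dosages count
#' ALT, matching [read_vcf()]. Requires hard calls 0/1/2/NA.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  if (!all(d[!is.na(d)] %in% c(0, 1, 2)))
    stop("write_vcf requires hard-call dosages 0/1/2/NA")
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  v <- gm$variants
  recs <- vapply(seq_len(ncol(d)), function(k) {
    gts <- gt_map[as.character(d[, k])]
    gts[is.na(gts)] <- "./."
    paste(c(v$chrom[k], v$pos[k], v$vid[k], v$allele_a[k], v$allele_b[k],
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t"),
    recs), path)
  invisible(path)
}

#' Read / write a variant weight table (TSV)
#'
#' Tab-separated with header `vid, effect_allele, other_allele, weight,
#' source`; `weight` is a natural-log odds ratio.
#'
#' @param path file path.
#' @return [read_weight_table()] returns a [weight_table()].
#' @export
read_weight_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("vid", "effect_allele", "other_allele", "weight")
  if (!all(req %in% names(df)))
    stop("weight table needs columns: ", paste(req, collapse = ", "))
  if (is.null(df$source)) df$source <- "gwas"
  weight_table(df$vid, df$effect_allele, df$other_allele, df$weight,
               df$source)
}

#' @rdname read_weight_table
#' @param wt a [weight_table()].
#' @export
write_weight_table <- function(wt, path) {
  utils::write.table(as.data.frame(wt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort phenotype table (CSV)
#'
#' @param path file path.
#' @return [read_cohort_table()] returns a [cohort_table()].
#' @export
read_cohort_table <- function(path) {
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort_table
#' @param cohort a [cohort_table()].
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize a genotype matrix to a weight table's effect alleles
#'
#' Aligns every shared variant so that its dosage counts the weight
#' table's effect allele: variants already counting the effect allele are
#' kept as-is; variants counting the other allele are flipped
#' (`g -> 2 - g`, alleles swapped); variants whose allele pair cannot be
#' reconciled are dropped. Palindromic (A/T, C/G) variants are strand-
#' ambiguous and handled per `ambiguous_policy`. Variants absent from the
#' weight table are dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param wt a [weight_table()].
#' @param ambiguous_policy `"drop"` (default; warn and drop palindromic
#'   variants) or `"keep"` (trust the file strand).
#' @return A list of class `harmonization` with elements `genotypes`
#'   (aligned `genotype_matrix`) and `report` (data.frame with per-variant
#'   `vid`, `action` in kept/flipped/dropped, `reason`).
#' @export
harmonize <- function(gm, wt, ambiguous_policy = c("drop", "keep")) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(wt, "weight_table"))
  ambiguous_policy <- match.arg(ambiguous_policy)
  idx <- match(gm$variants$vid, wt$vid)
  in_wt <- !is.na(idx)
  if (!any(in_wt)) stop("no overlapping variants between genotypes and weight table")

  v <- gm$variants
  action <- ifelse(in_wt, "kept", "dropped")
  reason <- ifelse(in_wt, "", "not in weight table")
  flip <- logical(nrow(v))

  for (k in which(in_wt)) {
    ea <- wt$effect_allele[idx[k]]; oa <- wt$other_allele[idx[k]]
    pal <- is_palindromic(v$allele_a[k], v$allele_b[k])
    if (pal && ambiguous_policy == "drop") {
      action[k] <- "dropped"; reason[k] <- "palindromic"
      next
    }
    if (v$allele_b[k] == ea && v$allele_a[k] == oa) {
      # already counts the effect allele
    } else if (v$allele_a[k] == ea && v$allele_b[k] == oa) {
      flip[k] <- TRUE; action[k] <- "flipped"
    } else {
      action[k] <- "dropped"; reason[k] <- "allele mismatch"
    }
  }
  n_pal <- sum(reason == "palindromic")
  if (n_pal) warning(n_pal, " palindromic variant(s) dropped (strand ambiguous)")

  keep <- action != "dropped"
  if (!any(keep)) stop("no variants survive harmonization")
  dos <- gm$dosages[, keep, drop = FALSE]
  vk <- v[keep, , drop = FALSE]
  fk <- flip[keep]
  if (any(fk)) {
    dos[, fk] <- 2 - dos[, fk]
    tmp <- vk$allele_a[fk]
    vk$allele_a[fk] <- vk$allele_b[fk]
    vk$allele_b[fk] <- tmp
  }
  out <- genotype_matrix(dos, vk, gm$sample_ids, allow_real = TRUE)
  structure(list(genotypes = out,
                 report = data.frame(vid = v$vid, action = action,
                                     reason = reason,
                                     stringsAsFactors = FALSE)),
            class = "harmonization")
}
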