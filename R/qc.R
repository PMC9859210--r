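## Trio quality control: Mendelian screening, call-rate filters,
## cross-platform concordance, and the demographic-table exact test.

#' QC thresholds
#'
#' SNPs with a call rate below 95% and samples below 70% are removed;
#' SNPs and families with Mendelian error rates of 5% or more can be
#' dropped (independent switches, both on by default).
#'
#' @param snp_call_rate_min,sample_call_rate_min call-rate floors.
#' @param family_mendel_rate_max,snp_mendel_rate_max Mendelian error
#'   rate caps (set to `NULL` to disable either).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(snp_call_rate_min = 0.95, sample_call_rate_min = 0.70,
                      family_mendel_rate_max = 0.05,
                      snp_mendel_rate_max = 0.05) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg) >= 0 & unlist(cfg) <= 1))
  class(cfg) <- "qc_config"
  cfg
}

#' Mendelian consistency of one genotype triple
#'
#' `inconsistent` iff no pair of transmitted alleles from the observed
#' parents can produce the child dosage.  With one parent missing the
#' child is tested against the observed parent alone, so a missing
#' member never creates a false inconsistency.  `untestable` when the
#' child (or both parents) is missing.
#'
#' @param m,f,c dosages in `{0, 1, 2, NA}` (vectorised).
#' @return character vector: `"consistent"`, `"inconsistent"` or
#'   `"untestable"`.
#' @export
mendelian_check <- function(m, f, c) {
  n <- max(length(m), length(f), length(c))
  m <- rep_len(m, n); f <- rep_len(f, n); c <- rep_len(c, n)
  out <- rep("consistent", n)
  untest <- is.na(c) | (is.na(m) & is.na(f))
  out[untest] <- "untestable"
  idx <- which(!untest)
  for (i in idx) {
    ms <- if (is.na(m[i])) 0:2 else m[i]
    fs <- if (is.na(f[i])) 0:2 else f[i]
    compat <- any(outer(ms, fs, function(a, b)
      transmission_prob(a, b, rep(c[i], length(a)))) > 0)
    if (!compat) out[i] <- "inconsistent"
  }
  out
}

#' Run dataset-level QC
#'
#' Order of operations: (1) Mendelian-inconsistent trio genotypes are
#' set to missing for the whole trio at that site, (2) SNPs/families
#' exceeding the Mendel-rate caps are dropped, (3) SNPs below the SNP
#' call-rate floor are dropped, (4) samples below the sample call-rate
#' floor are dropped.  Masking precedes the call-rate filters because
#' it changes call rates.
#'
#' @param dataset a [trio_dataset()].
#' @param config a [qc_config()].
#' @return list with `dataset` (cleaned) and `report` (class
#'   `qc_report`): per-step removal lists, rates, and the count of
#'   genotypes set to missing.
#' @export
qc_dataset <- function(dataset, config = qc_config()) {
  fam <- dataset$families
  nv <- nrow(dataset$geno)

  ## step 1: Mendelian masking
  masked <- 0L
  mendel_err <- matrix(0L, nv, nrow(fam))   # 1 = inconsistent at (snp, family)
  mendel_tested <- matrix(0L, nv, nrow(fam))
  for (i in seq_len(nrow(fam))) {
    cols <- stats::na.omit(c(fam$mother[i], fam$father[i], fam$child[i]))
    if (!length(cols)) next
    m <- if (is.na(fam$mother[i])) rep(NA_integer_, nv) else dataset$geno[, fam$mother[i]]
    f <- if (is.na(fam$father[i])) rep(NA_integer_, nv) else dataset$geno[, fam$father[i]]
    c <- if (is.na(fam$child[i])) rep(NA_integer_, nv) else dataset$geno[, fam$child[i]]
    st <- mendelian_check(m, f, c)
    mendel_tested[, i] <- st != "untestable"
    bad <- which(st == "inconsistent")
    if (length(bad)) {
      mendel_err[bad, i] <- 1L
      dataset$geno[bad, cols] <- NA_integer_
      masked <- masked + length(bad) * length(cols)
    }
  }

  ## step 2: Mendel-rate caps
  removed_snps <- character(0)
  removed_families <- character(0)
  snp_mendel <- rowSums(mendel_err) / pmax(rowSums(mendel_tested), 1)
  fam_mendel <- colSums(mendel_err) / pmax(colSums(mendel_tested), 1)
  if (!is.null(config$snp_mendel_rate_max)) {
    drop <- snp_mendel >= config$snp_mendel_rate_max & rowSums(mendel_tested) > 0
    removed_snps <- c(removed_snps, rownames(dataset$geno)[drop])
  }
  if (!is.null(config$family_mendel_rate_max)) {
    dropf <- fam_mendel >= config$family_mendel_rate_max & colSums(mendel_tested) > 0
    removed_families <- fam$fid[dropf]
  }

  ## step 3: SNP call rate (on masked data, surviving families' samples)
  keep_fam <- !(fam$fid %in% removed_families)
  samp <- unlist(fam[keep_fam, c("mother", "father", "child")])
  samp <- samp[!is.na(samp)]
  g <- dataset$geno[, samp, drop = FALSE]
  snp_call <- rowMeans(!is.na(g))
  removed_snps <- union(removed_snps,
                        rownames(g)[snp_call < config$snp_call_rate_min])

  ## step 4: sample call rate (on surviving SNPs)
  keep_snp <- setdiff(rownames(g), removed_snps)
  g2 <- g[keep_snp, , drop = FALSE]
  sample_call <- colMeans(!is.na(g2))
  removed_samples <- colnames(g2)[sample_call < config$sample_call_rate_min]

  keep_samp <- setdiff(colnames(dataset$geno)[colnames(dataset$geno) %in% samp],
                       removed_samples)
  clean_fam <- fam[keep_fam, , drop = FALSE]
  for (role in c("mother", "father", "child"))
    clean_fam[[role]][!(clean_fam[[role]] %in% keep_samp)] <- NA_character_
  keep2 <- !(is.na(clean_fam$mother) & is.na(clean_fam$father) &
               is.na(clean_fam$child))
  clean_fam <- clean_fam[keep2, , drop = FALSE]
  expo <- dataset$exposure
  if (!is.null(expo)) expo <- expo[expo$family_id %in% clean_fam$fid, , drop = FALSE]

  clean <- trio_dataset(dataset$geno[keep_snp, keep_samp, drop = FALSE],
                        dataset$variants[match(keep_snp, dataset$variants$id), , drop = FALSE],
                        clean_fam, expo, dataset$truth, dataset$quality)
  report <- structure(list(
    genotypes_masked = masked,
    snp_mendel_rate = snp_mendel, family_mendel_rate = fam_mendel,
    snp_call_rate = snp_call, sample_call_rate = sample_call,
    removed_snps = removed_snps, removed_families = removed_families,
    removed_samples = removed_samples), class = "qc_report")
  list(dataset = clean, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("trio QC report\n",
      "  genotypes masked (Mendelian): ", x$genotypes_masked, "\n",
      "  SNPs removed: ", length(x$removed_snps), "\n",
      "  families removed: ", length(x$removed_families), "\n",
      "  samples removed: ", length(x$removed_samples), "\n", sep = "")
  invisible(x)
}

#' Genotype concordance between two call sets
#'
#' Fraction of equal calls among mutually non-missing (variant, sample)
#' pairs; pairs with a missing value are excluded from the denominator.
#'
#' @param a,b dosage matrices (or vectors) over the same index set.
#' @return fraction in `[0, 1]`, or `NA` (with a warning) when no pair
#'   is comparable.
#' @export
genotype_concordance <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    warning("no mutually non-missing pairs; concordance undefined")
    return(NA_real_)
  }
  mean(a[ok] == b[ok])
}

#' Two-sided Fisher's exact test on an r x c table
#'
#' Exact p-value under the hypergeometric null with fixed margins,
#' summing the probabilities of all tables no more probable than the
#' observed one (the standard two-sided convention).  Wraps
#' `stats::fisher.test`; tables needing more than about 1e7 network
#' evaluations are rejected with a suggestion to use simulation.
#'
#' @param tab matrix of non-negative integers, at least 2 x 2.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 2, all(tab >= 0), sum(tab) > 0)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  ## enumeration-size guard: margin-bounded ranges of the free cells
  free <- outer(rowSums(tab)[-nrow(tab)], colSums(tab)[-ncol(tab)], pmin)
  size <- prod(free + 1)
  if (size > 1e7)
    stop("table too large for exact enumeration; use Monte-Carlo ",
         "(fisher.test(..., simulate.p.value = TRUE))")
  stats::fisher.test(tab)$p.value
}
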