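## The in-memory container exchanged between the simulator, QC and the
## association machinery.  Deliberately plain: a dosage matrix plus the
## family, exposure and (for simulated data) truth tables.

#' Construct a trio dataset
#'
#' Bundles a genotype dosage matrix with its family structure, the
#' per-family binary folate-supplementation exposure, and an optional
#' truth record carried along by the simulator.
#'
#' @param geno integer matrix, variants x samples; entries 0/1/2 count
#'   minor-allele copies, `NA` is a missing call.  Row names are variant
#'   ids, column names sample ids.
#' @param variants data frame with one row per variant: columns `id`,
#'   `chrom`, `pos`, `ref`, `alt`, `is_indel`, plus any INFO annotations
#'   (`QD`, `FS`, `MQ`, `HaplotypeScore`, `MQRankSum`, `ReadPosRankSum`)
#'   and optionally `pop_af`.
#' @param families data frame with one row per family: columns `fid`,
#'   `mother`, `father`, `child` (sample ids, `NA` when the member is
#'   absent) and `affected` (logical; the child's case status).
#' @param exposure data frame with columns `family_id` and
#'   `folate_supplemented` (0/1).
#' @param truth optional list recording simulation ground truth (true
#'   relative risks, injected de novo events, injected genotype errors).
#' @param quality optional list of matrices aligned with `geno`
#'   (`GQ`, `DP`, `parent_alt_reads`) used by de novo candidate filters.
#' @return an object of class `trio_dataset`.
#' @export
trio_dataset <- function(geno, variants, families, exposure = NULL,
                         truth = NULL, quality = NULL) {
  stopifnot(is.matrix(geno), nrow(geno) == nrow(variants))
  if (is.null(rownames(geno))) rownames(geno) <- variants$id
  stopifnot(all(geno %in% c(0L, 1L, 2L) | is.na(geno)))
  dup <- unlist(families[, c("mother", "father", "child")])
  dup <- dup[!is.na(dup)]
  if (anyDuplicated(dup))
    stop("a sample id appears in more than one family role")
  structure(list(geno = geno, variants = variants, families = families,
                 exposure = exposure, truth = truth, quality = quality),
            class = "trio_dataset")
}

#' @export
print.trio_dataset <- function(x, ...) {
  cl <- family_classification(x$families)
  cat("trio_dataset:", nrow(x$variants), "variants,",
      nrow(x$families), "families (",
      sum(cl == "complete trio"), "complete trios ),",
      ncol(x$geno), "samples\n")
  if (!is.null(x$exposure)) {
    supp <- sum(x$exposure$folate_supplemented == 1)
    cat("  exposure: ", supp, " supplemented / ",
        nrow(x$exposure) - supp, " unsupplemented families\n", sep = "")
  }
  if (!is.null(x$truth)) cat("  simulation truth record attached\n")
  invisible(x)
}

#' Classify families by which members are present
#'
#' @param families a family table as in [trio_dataset()].
#' @return character vector: one of "complete trio",
#'   "mother-infant dyad", "father-infant dyad", "mother-father dyad",
#'   "mother singleton", "father singleton", "infant singleton".
#' @export
family_classification <- function(families) {
  has_m <- !is.na(families$mother)
  has_f <- !is.na(families$father)
  has_c <- !is.na(families$child)
  out <- character(nrow(families))
  out[has_m & has_f & has_c] <- "complete trio"
  out[has_m & !has_f & has_c] <- "mother-infant dyad"
  out[!has_m & has_f & has_c] <- "father-infant dyad"
  out[has_m & has_f & !has_c] <- "mother-father dyad"
  out[has_m & !has_f & !has_c] <- "mother singleton"
  out[!has_m & has_f & !has_c] <- "father singleton"
  out[!has_m & !has_f & has_c] <- "infant singleton"
  out
}

## dosage triples (m, f, c) for one variant across families; NA where a
## member is absent or the call is missing
family_dosages <- function(dataset, variant) {
  g <- dataset$geno[variant, ]
  fam <- dataset$families
  pick <- function(ids) ifelse(is.na(ids), NA, g[ids])
  data.frame(fid = fam$fid,
             m = as.integer(pick(fam$mother)),
             f = as.integer(pick(fam$father)),
             c = as.integer(pick(fam$child)),
             affected = fam$affected,
             stringsAsFactors = FALSE)
}

## exposure stratum per family, aligned with dataset$families
family_exposure <- function(dataset) {
  stopifnot(!is.null(dataset$exposure))
  idx <- match(dataset$families$fid, dataset$exposure$family_id)
  ifelse(dataset$exposure$folate_supplemented[idx] == 1,
         "exposed", "unexposed")
}

#' Minor allele frequency per variant
#'
#' Computed from non-missing calls; by default over founders (parents)
#' only, which avoids transmission-induced bias when the frequency gates
#' a rare-variant filter.  The counted (alt) allele is declared minor
#' when its frequency is <= 0.5, ties broken toward alt.
#'
#' @param dataset a [trio_dataset()].
#' @param founders_only count parental samples only (default `TRUE`).
#' @return numeric vector of minor-allele frequencies in `[0, 0.5]`.
#' @export
variant_maf <- function(dataset, founders_only = TRUE) {
  samp <- colnames(dataset$geno)
  if (founders_only) {
    keep <- c(dataset$families$mother, dataset$families$father)
    samp <- samp[samp %in% keep[!is.na(keep)]]
  }
  g <- dataset$geno[, samp, drop = FALSE]
  af <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  af[is.nan(af)] <- NA_real_
  pmin(af, 1 - af)
}
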