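## Standard-format plumbing: VCF (via vcfR), 6-column PED, exposure CSV,
## and the GATK-style variant hard filters.

INFO_FIELDS <- c("QD", "FS", "MQ", "HaplotypeScore", "MQRankSum",
                 "ReadPosRankSum")

#' Read a multi-sample VCF into a genotype dosage matrix
#'
#' Parses a VCF v4.2 file (GT per sample required), splits multiallelic
#' records into one biallelic record per alternate allele (dosages
#' recoded against that allele), and extracts the numeric INFO
#' annotations used by the hard filters.  Half-missing genotypes
#' (e.g. `0/.`) are treated as missing.
#'
#' @param path VCF file (plain text or gzip).
#' @param region optional `"chrom"` or `"chrom:start-end"` string; only
#'   overlapping records are kept.
#' @return list with `geno` (variants x samples integer dosage matrix,
#'   alt-allele counts, `NA` missing) and `variants` (annotation data
#'   frame as in [trio_dataset()]).
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in VCF: ", path)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)

  info <- lapply(INFO_FIELDS, function(f)
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = f))))
  names(info) <- INFO_FIELDS
  af_info <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "POPAF")))

  rows <- list()
  geno <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gt <- gt_raw[i, ]
    alleles <- strsplit(gt, "[/|]")
    for (a in seq_along(alts)) {
      id <- fix$ID[i]
      if (is.na(id) || id == ".") id <- paste0(fix$CHROM[i], ":", fix$POS[i])
      if (length(alts) > 1) id <- paste0(id, "_", alts[a])
      dos <- vapply(alleles, function(al) {
        if (length(al) < 2 || anyNA(al) || any(al == "."))
          return(NA_integer_)
        sum(al == as.character(a))
      }, integer(1))
      rows[[length(rows) + 1]] <- data.frame(
        id = id, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        is_indel = nchar(fix$REF[i]) != 1 || nchar(alts[a]) != 1,
        QD = info$QD[i], FS = info$FS[i], MQ = info$MQ[i],
        HaplotypeScore = info$HaplotypeScore[i],
        MQRankSum = info$MQRankSum[i],
        ReadPosRankSum = info$ReadPosRankSum[i],
        pop_af = af_info[i],
        stringsAsFactors = FALSE)
      geno[[length(geno) + 1]] <- dos
    }
  }
  variants <- do.call(rbind, rows)
  mat <- do.call(rbind, geno)
  dimnames(mat) <- list(variants$id, samples)

  if (!is.null(region)) {
    parts <- strsplit(region, "[:-]")[[1]]
    keep <- variants$chrom == parts[1]
    if (length(parts) == 3)
      keep <- keep & variants$pos >= as.integer(parts[2]) &
        variants$pos <= as.integer(parts[3])
    variants <- variants[keep, , drop = FALSE]
    mat <- mat[keep, , drop = FALSE]
  }
  list(geno = mat, variants = variants)
}

#' Write a genotype matrix as a VCF v4.2 file
#'
#' Emits one biallelic record per variant with GT per sample and the
#' hard-filter INFO annotations that are present in the variant table.
#'
#' @param geno variants x samples dosage matrix (0/1/2/`NA`).
#' @param variants variant annotation data frame (see [trio_dataset()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, variants, path) {
  stopifnot(nrow(geno) == nrow(variants))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=folatrio",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description="Haplotype score">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(geno)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    kv <- character(0)
    for (f in INFO_FIELDS)
      if (!is.null(v[[f]]) && !is.na(v[[f]]))
        kv <- c(kv, paste0(f, "=", format(v[[f]], scientific = FALSE)))
    if (!is.null(v$pop_af) && !is.na(v$pop_af))
      kv <- c(kv, paste0("POPAF=", v$pop_af))
    info <- if (length(kv)) paste(kv, collapse = ";") else "."
    gts <- ifelse(is.na(geno[i, ]), "./.", gt_code[geno[i, ] + 1L])
    writeLines(paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS",
                       info, "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a 6-column PED/FAM pedigree into a family table
#'
#' Columns: FID, IID, father, mother, sex (1 = male, 2 = female),
#' phenotype (2 = affected).  A row with non-zero parent ids (or an
#' affected individual) is taken as the child; remaining members are
#' assigned the mother/father role by their sex code.  A parent id
#' referenced by a child but absent from the file triggers a warning
#' and the parent is recorded as absent.
#'
#' @param path PED file, whitespace-delimited, no header.
#' @return data frame with columns `fid`, `mother`, `father`, `child`,
#'   `affected` and `classification` (see [family_classification()]).
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "father", "mother",
                                         "sex", "phenotype"))
  ped$fid <- as.character(ped$fid)
  ped$iid <- as.character(ped$iid)
  ped$father <- as.character(ped$father)
  ped$mother <- as.character(ped$mother)
  if (anyDuplicated(ped$iid))
    stop("duplicate individual id in pedigree: ",
         paste(unique(ped$iid[duplicated(ped$iid)]), collapse = ", "))
  fams <- lapply(split(ped, ped$fid), function(p) {
    is_child <- p$father != "0" | p$mother != "0" | p$phenotype == 2
    child_row <- which(is_child)[1]  # at most one child per family here
    mother <- father <- child <- NA_character_
    affected <- NA
    if (!is.na(child_row)) {
      child <- p$iid[child_row]
      affected <- p$phenotype[child_row] == 2
      for (role in c("mother", "father")) {
        pid <- p[[role]][child_row]
        if (pid != "0") {
          if (pid %in% p$iid) {
            if (role == "mother") mother <- pid else father <- pid
          } else {
            warning("family ", p$fid[1], ": ", role, " id '", pid,
                    "' not in pedigree; treated as absent")
          }
        }
      }
      rest <- p$iid[-child_row]
    } else {
      rest <- p$iid
    }
    rest <- setdiff(rest, c(mother, father))
    for (iid in rest) {
      sx <- p$sex[p$iid == iid]
      if (sx == 2 && is.na(mother)) mother <- iid
      else if (sx == 1 && is.na(father)) father <- iid
    }
    data.frame(fid = p$fid[1], mother = mother, father = father,
               child = child, affected = affected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fams)
  rownames(out) <- NULL
  out$classification <- family_classification(out)
  out
}

#' Write a family table as a 6-column PED file
#'
#' @param families family table as in [trio_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(families, path) {
  rows <- character(0)
  for (i in seq_len(nrow(families))) {
    f <- families[i, ]
    if (!is.na(f$mother))
      rows <- c(rows, paste(f$fid, f$mother, 0, 0, 2, 1))
    if (!is.na(f$father))
      rows <- c(rows, paste(f$fid, f$father, 0, 0, 1, 1))
    if (!is.na(f$child))
      rows <- c(rows, paste(f$fid, f$child,
                            ifelse(is.na(f$father), 0, f$father),
                            ifelse(is.na(f$mother), 0, f$mother),
                            1, ifelse(isTRUE(f$affected), 2, 1)))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read / write the per-family exposure table
#'
#' CSV with header `family_id,folate_supplemented` (0/1 coding for
#' periconceptional folic acid supplementation).
#'
#' @param path CSV file.
#' @return data frame with those two columns.
#' @export
read_exposure <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family_id", "folate_supplemented") %in% names(x)))
  x$family_id <- as.character(x$family_id)
  stopifnot(all(x$folate_supplemented %in% c(0, 1)))
  x
}

#' @rdname read_exposure
#' @param exposure exposure data frame.
#' @export
write_exposure <- function(exposure, path) {
  utils::write.csv(exposure[, c("family_id", "folate_supplemented")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hard-filter thresholds for variant-level QC
#'
#' GATK-style hard filters.  SNPs fail when QD < 2, FS > 60, MQ < 40,
#' HaplotypeScore > 13, MQRankSum < -12.5 or ReadPosRankSum < -8;
#' indels when QD < 2, FS > 200 or ReadPosRankSum < -20.  All
#' inequalities strict; a missing annotation skips that criterion.
#'
#' @param snp,indel named numeric vectors of thresholds (overrides).
#' @return list of class `hard_filter_config`.
#' @export
hard_filter_config <- function(snp = NULL, indel = NULL) {
  cfg <- list(
    snp = c(qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
            haplotype_score_max = 13.0, mq_rank_sum_min = -12.5,
            read_pos_rank_sum_min = -8.0),
    indel = c(qd_min = 2.0, fs_max = 200.0, read_pos_rank_sum_min = -20.0))
  if (!is.null(snp)) cfg$snp[names(snp)] <- snp
  if (!is.null(indel)) cfg$indel[names(indel)] <- indel
  stopifnot(all(is.finite(unlist(cfg))))
  class(cfg) <- "hard_filter_config"
  cfg
}

#' Apply variant hard filters
#'
#' A variant fails when ANY criterion for its class (SNP or indel) is
#' met; the fail list records every failed criterion.  Missing
#' annotations pass the corresponding criterion.
#'
#' @param variants variant annotation data frame.
#' @param config a [hard_filter_config()].
#' @return list with `pass` (data frame of passing variants) and `fail`
#'   (failing variants plus a `reasons` column).
#' @export
apply_hard_filters <- function(variants, config = hard_filter_config()) {
  fails <- function(value, thr, direction) {
    ok <- !is.na(value)
    out <- rep(FALSE, length(value))
    out[ok] <- if (direction == "lt") value[ok] < thr else value[ok] > thr
    out
  }
  tag <- function(field, thr, dir)
    paste0(field, if (dir == "lt") "<" else ">",
           format(unname(thr), nsmall = 1))
  reasons <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    r <- character(0)
    if (isTRUE(v$is_indel)) {
      t <- config$indel
      if (fails(v$QD, t["qd_min"], "lt"))
        r <- c(r, tag("QD", t["qd_min"], "lt"))
      if (fails(v$FS, t["fs_max"], "gt"))
        r <- c(r, tag("FS", t["fs_max"], "gt"))
      if (fails(v$ReadPosRankSum, t["read_pos_rank_sum_min"], "lt"))
        r <- c(r, tag("ReadPosRankSum", t["read_pos_rank_sum_min"], "lt"))
    } else {
      t <- config$snp
      if (fails(v$QD, t["qd_min"], "lt"))
        r <- c(r, tag("QD", t["qd_min"], "lt"))
      if (fails(v$FS, t["fs_max"], "gt"))
        r <- c(r, tag("FS", t["fs_max"], "gt"))
      if (fails(v$MQ, t["mq_min"], "lt"))
        r <- c(r, tag("MQ", t["mq_min"], "lt"))
      if (fails(v$HaplotypeScore, t["haplotype_score_max"], "gt"))
        r <- c(r, tag("HaplotypeScore", t["haplotype_score_max"], "gt"))
      if (fails(v$MQRankSum, t["mq_rank_sum_min"], "lt"))
        r <- c(r, tag("MQRankSum", t["mq_rank_sum_min"], "lt"))
      if (fails(v$ReadPosRankSum, t["read_pos_rank_sum_min"], "lt"))
        r <- c(r, tag("ReadPosRankSum", t["read_pos_rank_sum_min"], "lt"))
    }
    reasons[[i]] <- r
  }
  bad <- lengths(reasons) > 0
  fail <- variants[bad, , drop = FALSE]
  fail$reasons <- vapply(reasons[bad], paste, character(1), collapse = ";")
  list(pass = variants[!bad, , drop = FALSE], fail = fail)
}
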