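## End-to-end orchestration: QC -> per-SNP G-by-E -> two-phase meta +
## BFDP ranking -> rare-variant region scan -> de novo enrichment.
## Stages communicate through files with documented schemas so any
## stage can be rerun in isolation.

#' Read region definitions from a BED file
#'
#' BED is 0-based half-open; regions are converted to 1-based inclusive
#' coordinates internally.
#'
#' @param path BED file (chrom, start, end, name).
#' @return data frame with `region`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed$region <- if (ncol(bed) >= 4) bed[[4]] else
    paste0(bed$chrom, ":", bed$start + 1, "-", bed$end)
  data.frame(region = bed$region, chrom = bed$chrom,
             start = bed$start + 1L, end = bed$end,
             stringsAsFactors = FALSE)
}

## region_dataset assembled from a trio dataset restricted to a range
region_from_dataset <- function(dataset, region, chrom, start, end) {
  keep <- dataset$variants$chrom == chrom &
    dataset$variants$pos >= start & dataset$variants$pos <= end
  fam <- dataset$families
  complete <- !is.na(fam$mother) & !is.na(fam$father) & !is.na(fam$child) &
    fam$affected %in% TRUE
  fam <- fam[complete, , drop = FALSE]
  vids <- dataset$variants$id[keep]
  sub <- function(ids) t(dataset$geno[vids, ids, drop = FALSE])
  structure(list(region = region,
                 mother = sub(fam$mother), father = sub(fam$father),
                 child = sub(fam$child),
                 variants = dataset$variants[keep, , drop = FALSE]),
            class = "region_dataset")
}

#' Pipeline configuration
#'
#' @param phases list of phases; each a list with `vcf`, `ped`,
#'   `exposure` file paths.  Phase 1 is also used for the rare-variant
#'   and de novo stages.
#' @param regions_bed optional BED file of rare-variant regions.
#' @param mutation_rate per-trio regional mutation probability `p0`, or
#'   a vector of per-base rates (collapsed by
#'   [region_mutation_prob()]).
#' @param qc a [qc_config()].
#' @param bfdp a [bfdp_config()].
#' @param rare a [rare_test_config()].
#' @param denovo a [denovo_filter_config()].
#' @param n_trios_denovo trio count for the enrichment test (default:
#'   complete case trios in phase 1 after QC).
#' @param seed integer seed recorded in every output.
#' @param out_dir output directory (created).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(phases, regions_bed = NULL,
                            mutation_rate = NULL, qc = qc_config(),
                            bfdp = bfdp_config(), rare = rare_test_config(),
                            denovo = denovo_filter_config(),
                            n_trios_denovo = NULL, seed = 1L,
                            out_dir = tempfile("folatrio_run")) {
  for (ph in phases)
    for (f in c("vcf", "ped", "exposure"))
      if (!file.exists(ph[[f]]))
        stop("input does not exist: ", ph[[f]])
  structure(as.list(environment()), class = "pipeline_config")
}

load_phase <- function(ph) {
  v <- read_vcf(ph$vcf)
  fams <- read_pedigree(ph$ped)
  expo <- read_exposure(ph$exposure)
  trio_dataset(v$geno, v$variants,
               fams[, c("fid", "mother", "father", "child", "affected")],
               expo)
}

#' Run the full two-phase analysis
#'
#' Stages run in fixed order (hard filters + QC per phase, per-SNP
#' G-by-E scan per phase, fixed-effect meta-analysis of the interaction
#' contrasts with BFDP ranking, rare-variant region scan, de novo
#' enrichment); each stage's outputs are written as TSV before the next
#' starts, and a failing variant/region yields a flagged row, never an
#' abort.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`: per-stage counts, thresholds
#'   applied, the result tables, seed and elapsed time per stage.
#' @export
run_full <- function(config) {
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  tick <- function(expr) {
    t0 <- Sys.time()
    val <- expr
    list(value = val, seconds = as.numeric(Sys.time() - t0, units = "secs"))
  }
  out_file <- function(name) file.path(config$out_dir, name)
  wtsv <- function(x, name) {
    utils::write.table(x, out_file(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out_file(name)
  }

  ## stage 1: load + hard filters + QC per phase
  phases <- list()
  for (i in seq_along(config$phases)) {
    st <- tick({
      ds <- load_phase(config$phases[[i]])
      hf <- apply_hard_filters(ds$variants)
      keep <- hf$pass$id
      ds <- trio_dataset(ds$geno[keep, , drop = FALSE],
                         ds$variants[match(keep, ds$variants$id), , drop = FALSE],
                         ds$families, ds$exposure)
      qc <- qc_dataset(ds, config$qc)
      # masked, filtered genotypes re-emitted for downstream tools
      write_vcf(qc$dataset$geno, qc$dataset$variants,
                out_file(sprintf("phase%d_clean.vcf", i)))
      writeLines(jsonlite::toJSON(list(
        genotypes_masked = qc$report$genotypes_masked,
        removed_snps = qc$report$removed_snps,
        removed_families = qc$report$removed_families,
        removed_samples = qc$report$removed_samples),
        auto_unbox = TRUE), out_file(sprintf("phase%d_qc_report.json", i)))
      wtsv(data.frame(variant = hf$fail$id, reasons = hf$fail$reasons),
           sprintf("phase%d_hard_filter_fail.tsv", i))
      wtsv(data.frame(
        metric = c("variants_in", "variants_hard_filtered",
                   "variants_qc_removed", "genotypes_masked",
                   "families_in", "families_removed"),
        value = c(nrow(ds$variants) + nrow(hf$fail), nrow(hf$fail),
                  length(qc$report$removed_snps),
                  qc$report$genotypes_masked,
                  nrow(ds$families),
                  length(qc$report$removed_families))),
        sprintf("phase%d_qc_summary.tsv", i))
      qc
    })
    phases[[i]] <- st$value
    stages[[sprintf("phase%d_qc", i)]] <- st$seconds
  }

  ## stage 2: per-SNP G-by-E scan per phase
  scans <- list()
  for (i in seq_along(phases)) {
    st <- tick({
      sc <- scan_gxe(phases[[i]]$dataset)
      wtsv(sc, sprintf("phase%d_gxe.tsv", i))
      sc
    })
    scans[[i]] <- st$value
    stages[[sprintf("phase%d_gxe", i)]] <- st$seconds
  }

  ## stage 3: meta-analysis of the interaction contrast + BFDP
  st <- tick({
    shared <- Reduce(intersect, lapply(scans, function(s) s$variant))
    params <- grep("^delta_", names(scans[[1]]), value = TRUE)
    rows <- lapply(shared, function(v) {
      row <- data.frame(variant = v, stringsAsFactors = FALSE)
      best_p <- Inf
      for (pp in params) {
        nm <- sub("^delta_", "", pp)
        ests <- list()
        for (s in scans) {
          r <- s[s$variant == v, ]
          if (!is.na(r[[pp]]) && !is.na(r[[paste0("se_delta_", nm)]]))
            ests[[length(ests) + 1]] <-
              effect_estimate(r[[pp]], r[[paste0("se_delta_", nm)]])
        }
        if (!length(ests)) next
        mr <- fixed_effect_meta(ests)
        bf <- as.numeric(bfdp(mr$combined, config$bfdp))
        row[[paste0("rr_interaction_", nm)]] <- mr$combined$rr
        row[[paste0("p_meta_", nm)]] <- mr$p
        row[[paste0("bfdp_meta_", nm)]] <- bf
        if (!is.na(mr$p) && mr$p < best_p) {
          best_p <- mr$p
          row$p_meta <- mr$p
          row$bfdp_meta <- bf
        }
      }
      if (is.null(row$p_meta)) { row$p_meta <- NA; row$bfdp_meta <- NA }
      row
    })
    meta_tab <- do.call(rbind, rows)
    wtsv(meta_tab, "meta_bfdp.tsv")
    noteworthy <- rank_noteworthy(meta_tab, config$bfdp)
    wtsv(noteworthy, "noteworthy.tsv")
    list(meta = meta_tab, noteworthy = noteworthy)
  })
  meta_res <- st$value
  stages[["meta_bfdp"]] <- st$seconds

  ## stage 4: rare-variant region scan (phase 1 data)
  rare_tab <- NULL
  if (!is.null(config$regions_bed)) {
    st <- tick({
      beds <- read_regions_bed(config$regions_bed)
      regions <- lapply(seq_len(nrow(beds)), function(j)
        region_from_dataset(phases[[1]]$dataset, beds$region[j],
                            beds$chrom[j], beds$start[j], beds$end[j]))
      names(regions) <- beds$region
      tab <- region_scan(regions, config$rare)
      wtsv(tab, "rare_regions.tsv")
      tab
    })
    rare_tab <- st$value
    stages[["rare"]] <- st$seconds
  }

  ## stage 5: de novo enrichment (phase 1 data)
  denovo_res <- NULL
  if (!is.null(config$mutation_rate)) {
    st <- tick({
      cand <- detect_candidates(phases[[1]]$dataset, config$denovo)
      wtsv(cand, "denovo_candidates.tsv")
      fam <- phases[[1]]$dataset$families
      n_trios <- config$n_trios_denovo
      if (is.null(n_trios))
        n_trios <- sum(!is.na(fam$mother) & !is.na(fam$father) &
                         !is.na(fam$child) & fam$affected %in% TRUE)
      p0 <- if (length(config$mutation_rate) > 1)
        region_mutation_prob(config$mutation_rate) else config$mutation_rate
      enr <- denovo_enrichment(n_trios, nrow(cand), p0)
      writeLines(jsonlite::toJSON(list(
        n = enr$n, k = enr$k, p0 = enr$p0,
        p_value = format(enr$p_value, digits = 6, scientific = TRUE)),
        auto_unbox = TRUE), out_file("denovo_enrichment.json"))
      enr
    })
    denovo_res <- st$value
    stages[["denovo"]] <- st$seconds
  }

  report <- structure(list(
    seed = config$seed, out_dir = config$out_dir,
    stage_seconds = stages,
    thresholds = list(p_meta = 0.05,
                      bfdp = config$bfdp$noteworthy_threshold,
                      bonferroni = if (!is.null(rare_tab))
                        rare_tab$bonferroni_alpha[1] else NA),
    qc = lapply(phases, `[[`, "report"),
    gxe = scans, meta = meta_res$meta, noteworthy = meta_res$noteworthy,
    rare = rare_tab, denovo = denovo_res), class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("folatrio run (seed ", x$seed, ") -> ", x$out_dir, "\n", sep = "")
  for (nm in names(x$stage_seconds))
    cat(sprintf("  %-14s %6.2fs\n", nm, x$stage_seconds[[nm]]))
  cat("  noteworthy interactions:", nrow(x$noteworthy), "\n")
  if (!is.null(x$rare))
    cat("  rare regions significant (kernel):",
        sum(x$rare$kernel_significant, na.rm = TRUE), "\n")
  if (!is.null(x$denovo))
    cat("  de novo enrichment p =", format(x$denovo$p_value, digits = 3), "\n")
  invisible(x)
}

#' Generate an on-disk demo dataset with truth manifest
#'
#' Writes a small simulated study (replication-phase stratum sizes: 154
#' supplemented / 99 unsupplemented case trios, 40 control trios, 20
#' SNPs of which the first carries the lead-SNP effect sizes, 3 rare
#' regions) as VCF + PED + exposure CSV + region BED, together with a
#' JSON manifest of the simulation truth.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return list with the file paths and the truth manifest.
#' @export
make_demo <- function(dir = tempfile("folatrio_demo"), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(n_variants = 20,
                    rr_fetal_unexposed = c(1.41, rep(1, 19)),
                    rr_fetal_exposed = c(0.74, rep(1, 19)),
                    seed = seed)
  ds <- simulate_trios(cfg)
  vcf <- file.path(dir, "trios.vcf")
  ped <- file.path(dir, "trios.ped")
  csv <- file.path(dir, "exposure.csv")
  bed <- file.path(dir, "regions.bed")
  write_vcf(ds$geno, ds$variants, vcf)
  write_pedigree(ds$families, ped)
  write_exposure(ds$exposure, csv)
  ## three rare regions appended as separate VCF rows is unnecessary:
  ## regions simply partition the 20 SNPs by position for the demo
  pos <- ds$variants$pos
  cuts <- stats::quantile(pos, c(0, 1 / 3, 2 / 3, 1))
  writeLines(sprintf("chr15\t%d\t%d\tregion%d",
                     c(min(pos) - 1, floor(cuts[2]), floor(cuts[3])),
                     c(floor(cuts[2]), floor(cuts[3]), max(pos)),
                     1:3), bed)
  manifest <- list(
    seed = seed,
    n_case_exposed = cfg$n_case_exposed,
    n_case_unexposed = cfg$n_case_unexposed,
    n_control = cfg$n_control_trios,
    rr_fetal_unexposed = cfg$rr_fetal_unexposed,
    rr_fetal_exposed = cfg$rr_fetal_exposed,
    causal_variant = ds$variants$id[1])
  manifest_path <- file.path(dir, "truth.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             manifest_path)
  list(vcf = vcf, ped = ped, exposure = csv, regions_bed = bed,
       truth = manifest, truth_json = manifest_path, dir = dir)
}
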