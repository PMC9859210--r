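# Fixture builders shared across test files.  Everything is generated
# in code; nothing is read from disk except files the tests write.

# dataset with explicitly given trio dosages (one variant) and strata
dataset_from_trios <- function(m, f, c, stratum,
                               affected = rep(TRUE, length(m)),
                               variant_id = "snp001") {
  n <- length(m)
  fid <- sprintf("fam%04d", seq_len(n))
  fams <- data.frame(fid = fid,
                     mother = paste0(fid, "_m"),
                     father = paste0(fid, "_f"),
                     child = paste0(fid, "_c"),
                     affected = affected, stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, 1, 3 * n,
                 dimnames = list(variant_id,
                                 c(rbind(fams$mother, fams$father, fams$child))))
  geno[1, fams$mother] <- as.integer(m)
  geno[1, fams$father] <- as.integer(f)
  geno[1, fams$child] <- as.integer(c)
  # absent member (NA dosage supplied as NA) stays a missing call;
  # member-level absence is modelled by setting the id to NA
  vars <- data.frame(id = variant_id, chrom = "chr1", pos = 100L,
                     ref = "G", alt = "A", is_indel = FALSE,
                     QD = 20, FS = 1, MQ = 60, HaplotypeScore = 1,
                     MQRankSum = 0, ReadPosRankSum = 0, pop_af = NA_real_,
                     stringsAsFactors = FALSE)
  expo <- data.frame(family_id = fid,
                     folate_supplemented = as.integer(stratum == "exposed"))
  trio_dataset(geno, vars, fams, expo)
}

# a cell-count object built directly from a 15-cell count vector
counts_from_cells <- function(unexposed = NULL, exposed = NULL) {
  cells <- trio_cells()
  key <- paste(cells$m, cells$f, cells$c, sep = "/")
  counts <- matrix(0, nrow(cells), 2,
                   dimnames = list(key, c("unexposed", "exposed")))
  if (!is.null(unexposed)) counts[, "unexposed"] <- unexposed
  if (!is.null(exposed)) counts[, "exposed"] <- exposed
  structure(list(cells = cells, counts = counts,
                 control = counts * 0,
                 incomplete = data.frame(m = integer(0), f = integer(0),
                                         c = integer(0),
                                         stratum = character(0)),
                 variant = "toy"), class = "trio_cell_counts")
}

# hand-built rare-variant region: lists of per-variant mother/father/
# child dosage vectors (families x variants matrices)
region_from_matrices <- function(m, f, c, name = "toy_region") {
  vn <- sprintf("rv%03d", seq_len(ncol(m)))
  dimnames(m) <- dimnames(f) <- dimnames(c) <-
    list(sprintf("fam%04d", seq_len(nrow(m))), vn)
  structure(list(region = name, mother = m, father = f, child = c,
                 variants = data.frame(id = vn, stringsAsFactors = FALSE)),
            class = "region_dataset")
}

# independent Mendelian-consistency oracle: enumerate the alleles each
# parent can transmit; never uses transmission_prob()
mendel_oracle <- function(m, f, c) {
  from <- function(d) unique(c(if (d >= 1) 1, if (d <= 1) 0))
  possible <- outer(from(m), from(f), `+`)
  if (c %in% possible) "consistent" else "inconsistent"
}

# brute-force profile-likelihood grid oracle for the log-linear MLE.
# Profiles the mating-type parameters analytically (Poisson closed
# form) and scans (beta_fetal, beta_maternal) on a grid; exact argmax
# to the grid step because the profile log-likelihood is concave.
grid_oracle <- function(cells, counts, lo = -2, hi = 2, step = 1e-3) {
  scan <- function(bf_grid, bm_grid) {
    best <- c(-Inf, NA, NA)
    mts <- split(seq_len(nrow(cells)), cells$mt)
    for (bm in bm_grid) {
      # vectorise over bf for one bm
      ll <- rep(0, length(bf_grid))
      for (s in mts) {
        ns <- sum(counts[s])
        D <- rep(0, length(bf_grid))
        for (i in s)
          D <- D + cells$trans[i] *
            exp(bf_grid * cells$c[i] + bm * cells$m[i])
        if (ns > 0) ll <- ll + ns * log(ns / D) - ns
      }
      for (i in seq_len(nrow(cells)))
        if (counts[i] > 0)
          ll <- ll + counts[i] * (log(cells$trans[i]) +
                                    bf_grid * cells$c[i] + bm * cells$m[i])
      k <- which.max(ll)
      if (ll[k] > best[1]) best <- c(ll[k], bf_grid[k], bm)
    }
    best
  }
  coarse_step <- 5e-3
  coarse <- scan(seq(lo, hi, by = coarse_step), seq(lo, hi, by = coarse_step))
  fine <- scan(seq(max(lo, coarse[2] - 2 * coarse_step),
                   min(hi, coarse[2] + 2 * coarse_step), by = step),
               seq(max(lo, coarse[3] - 2 * coarse_step),
                   min(hi, coarse[3] + 2 * coarse_step), by = step))
  c(beta_fetal = fine[2], beta_maternal = fine[3])
}

# deterministic per-test seeds derived from a fixed suite seed
suite_seed <- function(offset = 0) 20260920 %% 2^28 + offset
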