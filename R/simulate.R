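## Trio simulator.  Emulates the study design: case-parent trios (plus a
## small control set), biallelic SNPs under HWE, a family-level binary
## folate exposure independent of genotype, and multiplicative fetal and
## maternal per-allele relative risks that may differ between exposure
## strata.  Case ascertainment is by rejection sampling: a simulated
## pregnancy is retained as a case with probability equal to its
## penetrance, which is exact under any penetrance without algebra.

#' Simulation configuration for common-variant trio datasets
#'
#' Defaults reproduce the replication-phase study conditions: 154
#' folate-supplemented and 99 unsupplemented case families, 40 control
#' families, allele frequency 0.3, and a fetal per-allele relative risk
#' of 1.41 among unexposed and 0.74 among exposed families (the lead
#' SNP effect sizes); maternal effects null.  Set
#' `n_case_exposed`/`n_case_unexposed` to `NULL` and use `n_case_trios`
#' with `exposure_prevalence` (default 0.6, the observed supplementation
#' fraction) to draw exposure at random instead.
#'
#' @param n_case_trios total case families when stratum sizes are drawn.
#' @param n_case_exposed,n_case_unexposed exact per-stratum case counts.
#' @param n_control_trios control families (retained irrespective of
#'   genotype).
#' @param allele_freq minor-allele frequency (recycled over variants).
#' @param n_variants number of independent SNPs.
#' @param exposure_prevalence P(family supplemented).
#' @param baseline_risk disease risk for dosage 0/0 (both strata).
#' @param rr_fetal_unexposed,rr_fetal_exposed,rr_maternal_unexposed,rr_maternal_exposed
#'   multiplicative per-allele relative risks (recycled over variants).
#' @param missing_rates named vector, probability each family member is
#'   entirely absent (creates dyads/singletons), MCAR.
#' @param mendel_error_rate per-genotype perturbation rate applied by
#'   [inject_missingness_and_errors()] when called through pipelines.
#' @param seed integer seed; same seed, same dataset.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_case_trios = 253, n_case_exposed = 154,
                       n_case_unexposed = 99, n_control_trios = 40,
                       allele_freq = 0.3, n_variants = 1,
                       exposure_prevalence = 0.6, baseline_risk = 0.05,
                       rr_fetal_unexposed = 1.41, rr_fetal_exposed = 0.74,
                       rr_maternal_unexposed = 1, rr_maternal_exposed = 1,
                       missing_rates = c(mother = 0, father = 0, child = 0),
                       mendel_error_rate = 0, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(allele_freq > 0 & allele_freq < 1),
            exposure_prevalence >= 0, exposure_prevalence <= 1,
            baseline_risk > 0,
            all(c(rr_fetal_unexposed, rr_fetal_exposed,
                  rr_maternal_unexposed, rr_maternal_exposed) > 0),
            all(missing_rates >= 0 & missing_rates <= 1),
            mendel_error_rate >= 0, mendel_error_rate <= 1)
  max_pen <- baseline_risk *
    max(rr_fetal_unexposed, rr_fetal_exposed, 1)^2 *
    max(rr_maternal_unexposed, rr_maternal_exposed, 1)^2
  if (max_pen > 1)
    stop("penetrance exceeds 1: lower baseline_risk or relative risks")
  class(cfg) <- "sim_config"
  cfg
}

## vectorised draw of one variant for n families: parents HWE(q), child
## by Mendelian transmission
draw_trio_geno <- function(n, q) {
  m <- stats::rbinom(n, 2, q)
  f <- stats::rbinom(n, 2, q)
  c <- stats::rbinom(n, 1, m / 2) + stats::rbinom(n, 1, f / 2)
  cbind(m = m, f = f, c = c)
}

#' Simulate a case-parent trio dataset
#'
#' Parental genotypes are drawn under Hardy-Weinberg equilibrium at the
#' configured allele frequency, children by Mendelian transmission, and
#' exposure per family independently of genotype.  A candidate family is
#' retained as a case with probability equal to its penetrance
#' `baseline_risk * rr_fetal^c * rr_maternal^m` for its stratum
#' (rejection sampling); control families are retained regardless of
#' genotype.  With several variants, penetrance multiplies over
#' variants.  Member-level missingness is applied afterwards (MCAR).
#'
#' @param config a [sim_config()].
#' @return a [trio_dataset()] whose `truth` records the configuration.
#' @export
simulate_trios <- function(config = sim_config()) {
  set.seed(config$seed)
  nv <- config$n_variants
  q <- rep_len(config$allele_freq, nv)
  rf0 <- rep_len(config$rr_fetal_unexposed, nv)
  rf1 <- rep_len(config$rr_fetal_exposed, nv)
  rm0 <- rep_len(config$rr_maternal_unexposed, nv)
  rm1 <- rep_len(config$rr_maternal_exposed, nv)

  if (!is.null(config$n_case_exposed) && !is.null(config$n_case_unexposed)) {
    strata <- c(exposed = config$n_case_exposed,
                unexposed = config$n_case_unexposed)
  } else {
    ne <- stats::rbinom(1, config$n_case_trios, config$exposure_prevalence)
    strata <- c(exposed = ne, unexposed = config$n_case_trios - ne)
  }

  sample_cases <- function(n_target, exposed) {
    rf <- if (exposed) rf1 else rf0
    rm <- if (exposed) rm1 else rm0
    out <- vector("list", 0)
    got <- 0
    while (got < n_target) {
      batch <- max(1000L, ceiling((n_target - got) / config$baseline_risk / 2))
      gl <- lapply(seq_len(nv), function(j) draw_trio_geno(batch, q[j]))
      pen <- rep(config$baseline_risk, batch)
      for (j in seq_len(nv))
        pen <- pen * rf[j]^gl[[j]][, "c"] * rm[j]^gl[[j]][, "m"]
      keep <- stats::runif(batch) < pen
      if (any(keep)) {
        out[[length(out) + 1]] <-
          lapply(gl, function(g) g[keep, , drop = FALSE])
        got <- got + sum(keep)
      }
    }
    # bind batches, trim to target
    lapply(seq_len(nv), function(j) {
      g <- do.call(rbind, lapply(out, `[[`, j))
      g[seq_len(n_target), , drop = FALSE]
    })
  }

  case_e <- sample_cases(strata["exposed"], TRUE)
  case_u <- sample_cases(strata["unexposed"], FALSE)
  ctrl <- lapply(seq_len(nv), function(j)
    draw_trio_geno(config$n_control_trios, q[j]))

  n_case <- sum(strata)
  n_fam <- n_case + config$n_control_trios
  fid <- sprintf("fam%04d", seq_len(n_fam))
  families <- data.frame(
    fid = fid,
    mother = paste0(fid, "_m"), father = paste0(fid, "_f"),
    child = paste0(fid, "_c"),
    affected = c(rep(TRUE, n_case), rep(FALSE, config$n_control_trios)),
    stringsAsFactors = FALSE)
  exposure <- data.frame(
    family_id = fid,
    folate_supplemented = c(rep(1L, strata["exposed"]),
                            rep(0L, strata["unexposed"]),
                            stats::rbinom(config$n_control_trios, 1,
                                          config$exposure_prevalence)))

  geno <- matrix(NA_integer_, nrow = nv, ncol = 3 * n_fam)
  colnames(geno) <- c(rbind(families$mother, families$father, families$child))
  for (j in seq_len(nv)) {
    g <- rbind(case_e[[j]], case_u[[j]], ctrl[[j]])
    geno[j, families$mother] <- g[, "m"]
    geno[j, families$father] <- g[, "f"]
    geno[j, families$child] <- g[, "c"]
  }
  variants <- data.frame(
    id = sprintf("snp%03d", seq_len(nv)), chrom = "chr15",
    pos = 80150000L + 100L * seq_len(nv), ref = "G", alt = "A",
    is_indel = FALSE, QD = 20, FS = 1, MQ = 60, HaplotypeScore = 1,
    MQRankSum = 0, ReadPosRankSum = 0, pop_af = NA_real_,
    stringsAsFactors = FALSE)
  rownames(geno) <- variants$id

  # member-level missingness -> dyads/singletons
  for (role in c("mother", "father", "child")) {
    r <- config$missing_rates[[role]]
    if (r > 0) {
      drop <- stats::runif(n_fam) < r
      gone <- families[[role]][drop]
      geno <- geno[, !(colnames(geno) %in% gone), drop = FALSE]
      families[[role]][drop] <- NA_character_
    }
  }
  keep_fam <- !(is.na(families$mother) & is.na(families$father) &
                  is.na(families$child))
  families <- families[keep_fam, , drop = FALSE]
  exposure <- exposure[keep_fam, , drop = FALSE]

  truth <- list(config = config,
                rr_fetal_unexposed = rf0, rr_fetal_exposed = rf1,
                rr_maternal_unexposed = rm0, rr_maternal_exposed = rm1,
                denovo = data.frame(fid = character(0),
                                    variant = character(0)),
                errors = data.frame(fid = character(0), sample = character(0),
                                    variant = character(0),
                                    old = integer(0), new = integer(0)))
  trio_dataset(geno, variants, families, exposure, truth)
}

#' Inject de novo mutations into a simulated dataset
#'
#' Each trio is selected independently with probability `per_trio_rate`;
#' for a selected trio one site where both parents are homozygous
#' reference (and the child currently carries dosage 0) is chosen at
#' random and the child call is set to heterozygous.  Every injection is
#' recorded in the truth list and is Mendelian-inconsistent by
#' construction.
#'
#' @param dataset a [trio_dataset()] with truth record.
#' @param per_trio_rate probability in `[0, 1]`.
#' @return the modified dataset.
#' @export
inject_denovo <- function(dataset, per_trio_rate) {
  stopifnot(per_trio_rate >= 0, per_trio_rate <= 1)
  if (per_trio_rate == 0) return(dataset)
  fam <- dataset$families
  complete <- !is.na(fam$mother) & !is.na(fam$father) & !is.na(fam$child)
  hit <- which(complete & stats::runif(nrow(fam)) < per_trio_rate)
  for (i in hit) {
    m <- dataset$geno[, fam$mother[i]]
    f <- dataset$geno[, fam$father[i]]
    c <- dataset$geno[, fam$child[i]]
    elig <- which(!is.na(m) & !is.na(f) & !is.na(c) & m == 0 & f == 0 & c == 0)
    if (!length(elig)) {
      warning("family ", fam$fid[i], ": no eligible de novo site; skipped")
      next
    }
    v <- if (length(elig) == 1) elig else sample(elig, 1)
    dataset$geno[v, fam$child[i]] <- 1L
    dataset$truth$denovo <- rbind(
      dataset$truth$denovo,
      data.frame(fid = fam$fid[i], variant = rownames(dataset$geno)[v],
                 stringsAsFactors = FALSE))
  }
  dataset
}

#' Inject missing calls and genotyping errors
#'
#' Deletes individual genotype calls at random per role (MCAR) and
#' perturbs calls to a different random dosage at rate
#' `mendel_error_rate`, recording every perturbation in the truth list.
#' Perturbations give downstream Mendelian screening something to find;
#' not all of them create an impossible trio.
#'
#' @param dataset a [trio_dataset()].
#' @param missing_rates named vector (`mother`, `father`, `child`) of
#'   per-call deletion probabilities.
#' @param mendel_error_rate per-call perturbation probability.
#' @return the modified dataset.
#' @export
inject_missingness_and_errors <- function(dataset,
                                          missing_rates = c(mother = 0, father = 0, child = 0),
                                          mendel_error_rate = 0) {
  stopifnot(all(missing_rates >= 0 & missing_rates <= 1),
            mendel_error_rate >= 0, mendel_error_rate <= 1)
  fam <- dataset$families
  for (role in c("mother", "father", "child")) {
    r <- missing_rates[[role]]
    if (r == 0) next
    cols <- fam[[role]][!is.na(fam[[role]])]
    sub <- dataset$geno[, cols, drop = FALSE]
    kill <- matrix(stats::runif(length(sub)) < r, nrow = nrow(sub))
    sub[kill] <- NA_integer_
    dataset$geno[, cols] <- sub
  }
  if (mendel_error_rate > 0) {
    g <- dataset$geno
    perturb <- which(!is.na(g) & matrix(stats::runif(length(g)) < mendel_error_rate,
                                        nrow = nrow(g)))
    samp_of <- colnames(g)[(perturb - 1) %/% nrow(g) + 1]
    var_of <- rownames(g)[(perturb - 1) %% nrow(g) + 1]
    role_lookup <- c(stats::setNames(fam$fid, fam$mother),
                     stats::setNames(fam$fid, fam$father),
                     stats::setNames(fam$fid, fam$child))
    for (k in seq_along(perturb)) {
      old <- g[perturb[k]]
      new <- sample(setdiff(0:2, old), 1)
      dataset$geno[perturb[k]] <- as.integer(new)
      dataset$truth$errors <- rbind(
        dataset$truth$errors,
        data.frame(fid = unname(role_lookup[samp_of[k]]),
                   sample = samp_of[k], variant = var_of[k],
                   old = as.integer(old), new = as.integer(new),
                   stringsAsFactors = FALSE))
    }
  }
  dataset
}

#' Configuration for rare-variant region simulation
#'
#' @param n_variants rare variants in the region.
#' @param n_families complete case trios.
#' @param maf_range founder minor-allele frequency range (upper bound
#'   must stay below 0.05, the rare-variant cut).
#' @param causal_fraction fraction of variants whose transmission is
#'   distorted.
#' @param effect_direction `"same"` (all risk) or `"mixed"` (half
#'   protective).
#' @param effect_size per-variant log-odds of transmission from a
#'   heterozygous parent (0.5 gives transmission probability ~0.62);
#'   default log(2).
#' @param seed integer seed.
#' @return list of class `rare_sim_config`.
#' @export
rare_sim_config <- function(n_variants = 30, n_families = 150,
                            maf_range = c(0.005, 0.045),
                            causal_fraction = 0, effect_direction = "same",
                            effect_size = log(2), seed = 1L) {
  stopifnot(maf_range[1] > 0, maf_range[2] < 0.05,
            causal_fraction >= 0, causal_fraction <= 1,
            effect_direction %in% c("same", "mixed"))
  structure(as.list(environment()), class = "rare_sim_config")
}

#' Simulate a rare-variant region for family-based tests
#'
#' Parental genotypes are drawn under HWE at per-variant MAFs inside
#' `maf_range`.  For non-causal variants heterozygous parents transmit
#' the minor allele with probability 1/2; for causal variants with
#' probability `plogis(effect)`, emulating the transmission distortion
#' that case ascertainment induces for risk (or protective) alleles.
#'
#' @param config a [rare_sim_config()].
#' @return list of class `region_dataset`: `region`, dosage matrices
#'   `mother`/`father`/`child` (families x variants), `variants` with
#'   founder MAF, and the truth effects.
#' @export
simulate_rare_region <- function(config = rare_sim_config()) {
  set.seed(config$seed)
  nv <- config$n_variants
  nf <- config$n_families
  maf <- stats::runif(nv, config$maf_range[1], config$maf_range[2])
  eff <- rep(0, nv)
  nc <- round(config$causal_fraction * nv)
  if (nc > 0) {
    idx <- seq_len(nc)
    s <- rep(1, nc)
    if (config$effect_direction == "mixed" && nc > 1)
      s[seq(1, nc, by = 2)] <- -1
    eff[idx] <- s * config$effect_size
  }
  m <- sapply(seq_len(nv), function(j) stats::rbinom(nf, 2, maf[j]))
  f <- sapply(seq_len(nv), function(j) stats::rbinom(nf, 2, maf[j]))
  pt <- stats::plogis(matrix(eff, nf, nv, byrow = TRUE))  # P(het parent transmits minor)
  tm <- matrix(stats::rbinom(nf * nv, 1, ifelse(m == 1, pt, m / 2)), nf, nv)
  tf <- matrix(stats::rbinom(nf * nv, 1, ifelse(f == 1, pt, f / 2)), nf, nv)
  child <- tm + tf
  vn <- sprintf("rv%03d", seq_len(nv))
  dimnames(m) <- dimnames(f) <- dimnames(child) <-
    list(sprintf("fam%04d", seq_len(nf)), vn)
  structure(list(
    region = "region1",
    mother = m, father = f, child = child,
    variants = data.frame(id = vn, maf_true = maf,
                          effect = eff, stringsAsFactors = FALSE),
    config = config), class = "region_dataset")
}
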