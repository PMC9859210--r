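# The exposure-stratified trio log-linear model.

test_that("tabulation places trios in their genotype cells", {
  ds <- dataset_from_trios(1, 1, 2, "unexposed")
  cc <- tabulate_trios(ds, "snp001")
  expect_equal(unname(cc$counts["1/1/2", "unexposed"]), 1)
  expect_equal(sum(cc$counts), 1)

  cells <- trio_cells()
  ds15 <- dataset_from_trios(cells$m, cells$f, cells$c,
                             rep("exposed", 15))
  cc15 <- tabulate_trios(ds15, "snp001")
  expect_true(all(cc15$counts[, "exposed"] == 1))
  expect_equal(nrow(cc15$cells), 15)
})

test_that("Mendelian-inconsistent trios are excluded with a warning", {
  ds <- dataset_from_trios(c(0, 1), c(0, 1), c(2, 1),
                           c("unexposed", "unexposed"))
  expect_warning(cc <- tabulate_trios(ds, "snp001"), "inconsistent")
  expect_equal(sum(cc$counts), 1)
})

test_that("incomplete families are stored verbatim, controls separately", {
  ds <- dataset_from_trios(c(1, 1, 0), c(1, NA, 0), c(2, 1, 0),
                           rep("unexposed", 3),
                           affected = c(TRUE, TRUE, FALSE))
  ds$families$father[2] <- NA
  cc <- tabulate_trios(ds, "snp001")
  expect_equal(sum(cc$counts), 1)
  expect_equal(nrow(cc$incomplete), 1)
  expect_equal(cc$incomplete$m, 1)
  expect_true(is.na(cc$incomplete$f))
  expect_equal(sum(cc$control), 1)
})

test_that("null counts proportional to transmission give zero genetic effects", {
  cells <- trio_cells()
  cc <- counts_from_cells(unexposed = 400 * cells$trans)
  fit <- trio_loglin(cc, "unexposed")
  expect_equal(unname(fit$coef), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(exp(fit$coef)), c(1, 1), tolerance = 1e-6)
})

test_that("the optimiser matches the brute-force profile-likelihood grid", {
  # four-cell toy table spanning two mating types so both effects are
  # identified: (1,1,1), (1,1,2), (1,2,1), (2,1,1)
  cells <- trio_cells()
  key <- paste(cells$m, cells$f, cells$c, sep = "/")
  n <- setNames(rep(0, 15), key)
  n[c("1/1/1", "1/1/2", "1/2/1", "2/1/1")] <- c(50, 30, 20, 40)
  cc <- counts_from_cells(unexposed = n)
  fit <- trio_loglin(cc, "unexposed")
  # the oracle profiles over the same support the fitter uses: every
  # cell of the mating types that carry data, zero counts included
  keep <- cells$mt %in% c("mt11", "mt12")
  oracle <- grid_oracle(cells[keep, ], n[keep])
  expect_lt(abs(fit$coef["beta_fetal"] - oracle["beta_fetal"]), 2e-3)
  expect_lt(abs(fit$coef["beta_maternal"] - oracle["beta_maternal"]), 2e-3)
})

test_that("conditional cell probabilities sum to one within each mating type", {
  ds <- simulate_trios(sim_config(n_case_exposed = 200, n_case_unexposed = 200,
                                  seed = suite_seed(30)))
  fit <- trio_loglin(tabulate_trios(ds, "snp001"), "unexposed")
  probs <- fit$cells$fitted / tapply(fit$cells$fitted, fit$cells$mt,
                                     sum)[fit$cells$mt]
  sums <- tapply(probs, fit$cells$mt, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-8)
})

test_that("EM with a single-cell-compatible family equals the complete-data fit", {
  ds <- simulate_trios(sim_config(n_case_exposed = 150, n_case_unexposed = 150,
                                  seed = suite_seed(31)))
  cc <- tabulate_trios(ds, "snp001")
  # parents (0,0) with child missing are compatible with cell (0,0,0)
  # only, so the EM must resolve the family exactly like an extra
  # complete (0,0,0) trio
  cc_em <- cc
  cc_em$incomplete <- rbind(cc_em$incomplete,
                            data.frame(m = 0, f = 0, c = NA,
                                       stratum = "unexposed"))
  fit_em <- trio_loglin(cc_em, "unexposed")
  cc_cd <- cc
  cc_cd$counts["0/0/0", "unexposed"] <- cc_cd$counts["0/0/0", "unexposed"] + 1
  fit_cd <- trio_loglin(cc_cd, "unexposed")
  expect_equal(fit_em$coef, fit_cd$coef, tolerance = 1e-10)
  expect_equal(fit_em$n_incomplete, 1)
})

test_that("EM log-likelihood is monotone and beats dropping incomplete families", {
  ds <- simulate_trios(sim_config(n_case_exposed = 250, n_case_unexposed = 250,
                                  seed = suite_seed(32)))
  set.seed(suite_seed(33))
  fam <- ds$families
  drop_f <- sample(nrow(fam), 120)
  ds$geno <- ds$geno[, !(colnames(ds$geno) %in% fam$father[drop_f]), drop = FALSE]
  ds$families$father[drop_f] <- NA
  cc <- tabulate_trios(ds, "snp001")
  expect_gt(nrow(cc$incomplete), 0)
  fit <- trio_loglin(cc, "unexposed")
  expect_true(all(diff(fit$em_trace) >= -1e-8))
  expect_true(fit$converged)
  fit_drop <- trio_loglin(cc, "unexposed", use_incomplete = FALSE)
  expect_lt(fit_drop$se["beta_fetal"] / fit$se["beta_fetal"], 1.5)
  expect_gt(fit$n_incomplete, 0)
  expect_equal(fit_drop$n_incomplete, 0)
})

test_that("fetal effect recovery at the lead-SNP effect size", {
  set.seed(suite_seed(34))
  cover <- logical(20)
  for (i in seq_len(20)) {
    ds <- simulate_trios(sim_config(n_case_exposed = 0, n_case_unexposed = 2000,
                                    n_control_trios = 0,
                                    seed = sample.int(2^30, 1)))
    fit <- trio_loglin(tabulate_trios(ds, "snp001"), "unexposed")
    ci <- confint(fit)["beta_fetal", ]
    cover[i] <- ci[1] <= log(1.41) && log(1.41) <= ci[2]
  }
  expect_gte(sum(cover), 17)   # 95% CIs; P(<17 of 20) < 0.003
})

test_that("without maternal effect the estimate agrees with a plain TDT", {
  ds <- simulate_trios(sim_config(n_case_exposed = 0, n_case_unexposed = 50000,
                                  n_control_trios = 0,
                                  seed = suite_seed(35)))
  fit <- trio_loglin(tabulate_trios(ds, "snp001"), "unexposed",
                     include_maternal = FALSE)
  d <- folatrio:::family_dosages(ds, "snp001")
  nhet <- (d$m == 1) + (d$f == 1)
  tr <- sum(d$c - (d$m == 2) - (d$f == 2))
  nt <- sum(nhet) - tr
  expect_lt(abs(exp(fit$coef["beta_fetal"]) / (tr / nt) - 1), 0.02)
})

test_that("fetal estimates tolerate population stratification", {
  # two subpopulations with very different allele frequencies, both
  # null: pooled mating-type counts are badly confounded for a
  # case-control contrast, but the within-family fetal effect stays 1
  mk <- function(q, seed) simulate_trios(sim_config(
    n_case_exposed = 0, n_case_unexposed = 5000, n_control_trios = 0,
    allele_freq = q, rr_fetal_unexposed = 1, rr_fetal_exposed = 1,
    seed = seed))
  cc1 <- tabulate_trios(mk(0.1, suite_seed(36)), "snp001")
  cc2 <- tabulate_trios(mk(0.5, suite_seed(37)), "snp001")
  pooled <- cc1
  pooled$counts <- cc1$counts + cc2$counts
  fit <- trio_loglin(pooled, "unexposed")
  expect_lt(abs(fit$coef["beta_fetal"]), 3 * fit$se["beta_fetal"])
})

test_that("the Wald interaction contrast reproduces hand arithmetic", {
  stub <- function(b, s, stratum) structure(
    list(coef = c(beta_fetal = b), se = c(beta_fetal = s),
         coding = "log-additive", include_maternal = FALSE,
         converged = FALSE, flags = "stub", stratum = stratum),
    class = "trio_loglin")
  res <- gxe_test(stub(log(1.41), 0.144, "unexposed"),
                  stub(log(0.74), 0.122, "exposed"),
                  counts_from_cells())
  expect_equal(round(res$estimates$z, 2), 3.42)
  expect_equal(res$estimates$p_wald, 6.3e-4, tolerance = 0.02)
  expect_false(res$reliable)   # stub fits are flagged, LRT skipped
  expect_true(is.na(res$p_lrt))

  same <- gxe_test(stub(0.2, 0.1, "unexposed"), stub(0.2, 0.1, "exposed"),
                   counts_from_cells())
  expect_equal(same$estimates$z, 0)
  expect_equal(same$estimates$p_wald, 1)
})

test_that("interaction detection works end to end on simulated data", {
  ds <- simulate_trios(sim_config(n_case_exposed = 500, n_case_unexposed = 500,
                                  seed = suite_seed(38)))
  cc <- tabulate_trios(ds, "snp001")
  f0 <- trio_loglin(cc, "unexposed")
  f1 <- trio_loglin(cc, "exposed")
  res <- gxe_test(f0, f1, cc)
  expect_true(res$reliable)
  expect_lt(res$estimates$p_wald[1], 0.01)
  expect_lt(res$p_lrt, 0.01)
  # LRT and Wald broadly agree
  expect_lt(abs(log10(res$p_lrt) - log10(min(res$estimates$p_wald))), 2)
})

test_that("scan table matches direct fits and flags degenerate variants", {
  ds <- simulate_trios(sim_config(n_case_exposed = 200, n_case_unexposed = 200,
                                  n_variants = 2, seed = suite_seed(39)))
  ds$geno[2, ] <- NA_integer_   # all-missing variant
  tab <- scan_gxe(ds)
  expect_equal(nrow(tab), 2)
  cc <- tabulate_trios(ds, "snp001")
  f0 <- trio_loglin(cc, "unexposed")
  row <- tab[tab$variant == "snp001", ]
  expect_equal(row$rr_fetal_unexposed, unname(exp(f0$coef["beta_fetal"])))
  expect_equal(row$flag, "")
  expect_equal(tab$flag[tab$variant == "snp002"], "untestable")
})

test_that("true interaction SNPs rank at the top of a mixed panel", {
  set.seed(suite_seed(40))
  hits <- integer(0)
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    rrs0 <- c(rep(1.41, 5), rep(1, 45))
    rrs1 <- c(rep(0.74, 5), rep(1, 45))
    ds <- simulate_trios(sim_config(n_case_exposed = 500,
                                    n_case_unexposed = 500,
                                    n_variants = 50,
                                    rr_fetal_unexposed = rrs0,
                                    rr_fetal_exposed = rrs1,
                                    seed = sample.int(2^30, 1)))
    tab <- scan_gxe(ds)
    top10 <- tab$variant[order(tab$p_lrt)][1:10]
    hits <- c(hits, sum(sprintf("snp%03d", 1:5) %in% top10))
  }
  expect_gte(mean(hits == 5), 0.9)
})

test_that("codominant coding nests the per-allele model", {
  ds <- simulate_trios(sim_config(n_case_exposed = 0, n_case_unexposed = 3000,
                                  n_control_trios = 0, seed = suite_seed(41)))
  cc <- tabulate_trios(ds, "snp001")
  add <- trio_loglin(cc, "unexposed")
  cod <- trio_loglin(cc, "unexposed", coding = "codominant")
  expect_length(cod$coef, 4)
  expect_gte(cod$loglik, add$loglik - 1e-8)  # richer model fits at least as well
  # single-copy codominant RR is close to the per-allele RR
  expect_equal(unname(cod$coef["beta_fetal1"]),
               unname(add$coef["beta_fetal"]), tolerance = 0.15)
})

test_that("model methods behave like standard fitted-model accessors", {
  ds <- simulate_trios(sim_config(n_case_exposed = 150, n_case_unexposed = 150,
                                  seed = suite_seed(42)))
  fit <- trio_loglin(tabulate_trios(ds, "snp001"), "unexposed")
  expect_named(coef(fit), c("beta_fetal", "beta_maternal"))
  expect_equal(dim(vcov(fit)), c(2, 2))
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(fit$se))
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(sum(fitted(fit)), fit$n_complete, tolerance = 1e-6)
  expect_equal(length(residuals(fit)), nrow(fit$cells))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(colSums(sims), rep(fit$n_complete, 3), ignore_attr = TRUE)
  expect_output(print(summary(fit)), "Relative risks")
})
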