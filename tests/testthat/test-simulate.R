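# The trio simulator: determinism, null symmetry, ascertainment
# distortion, stratum sizes, and the injection operators.

test_that("same seed gives bit-identical datasets, different seeds differ", {
  cfg <- sim_config(n_case_exposed = 40, n_case_unexposed = 40,
                    n_variants = 3, seed = suite_seed(10))
  a <- simulate_trios(cfg)
  b <- simulate_trios(cfg)
  expect_identical(a$geno, b$geno)
  expect_identical(a$exposure, b$exposure)
  cfg2 <- cfg; cfg2$seed <- suite_seed(11)
  c <- simulate_trios(cfg2)
  expect_false(identical(a$geno, c$geno))
  expect_identical(dim(a$geno), dim(c$geno))
})

test_that("under the null, heterozygous parents transmit the minor allele at 1/2", {
  ds <- simulate_trios(sim_config(n_case_trios = 20000, n_case_exposed = NULL,
                                  n_case_unexposed = NULL,
                                  n_control_trios = 0, allele_freq = 0.3,
                                  rr_fetal_unexposed = 1, rr_fetal_exposed = 1,
                                  seed = suite_seed(12)))
  d <- folatrio:::family_dosages(ds, "snp001")
  nhet <- (d$m == 1) + (d$f == 1)
  tr <- d$c - (d$m == 2) - (d$f == 2)
  tot <- sum(nhet)
  frac <- sum(tr) / tot
  se <- sqrt(0.25 / tot)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("case-child genotype distribution matches the enumerated ascertainment model", {
  # fetal RR 2 among unexposed: cell probabilities proportional to
  # HWE(m) HWE(f) T(c|m,f) 2^c, enumerated exactly over the 15 cells
  q <- 0.3
  ds <- simulate_trios(sim_config(n_case_exposed = 0, n_case_unexposed = 20000,
                                  n_control_trios = 0, allele_freq = q,
                                  rr_fetal_unexposed = 2, rr_fetal_exposed = 1,
                                  seed = suite_seed(13)))
  cells <- trio_cells()
  hwe <- function(g) dbinom(g, 2, q)
  expect_prob <- hwe(cells$m) * hwe(cells$f) * cells$trans * 2^cells$c
  expect_prob <- expect_prob / sum(expect_prob)
  cc <- tabulate_trios(ds, "snp001")
  obs <- cc$counts[, "unexposed"]
  expect_equal(sum(obs), 20000)
  chi <- suppressWarnings(chisq.test(obs, p = expect_prob))
  expect_gt(chi$p.value, 0.01)
})

test_that("configured stratum sizes appear exactly in the exposure table", {
  ds <- simulate_trios(sim_config(seed = suite_seed(14)))
  expo <- ds$exposure[ds$families$affected, ]
  expect_equal(sum(expo$folate_supplemented == 1), 154)
  expect_equal(sum(expo$folate_supplemented == 0), 99)
})

test_that("generated complete trios are Mendelian-consistent before injection", {
  ds <- simulate_trios(sim_config(n_case_exposed = 100, n_case_unexposed = 100,
                                  n_variants = 5, seed = suite_seed(15)))
  for (v in rownames(ds$geno)) {
    d <- folatrio:::family_dosages(ds, v)
    expect_true(all(mendelian_check(d$m, d$f, d$c) == "consistent"))
  }
})

test_that("with all relative risks 1, case and control cell distributions agree", {
  ds <- simulate_trios(sim_config(n_case_trios = 20000, n_case_exposed = NULL,
                                  n_case_unexposed = NULL,
                                  n_control_trios = 20000,
                                  rr_fetal_unexposed = 1, rr_fetal_exposed = 1,
                                  seed = suite_seed(16)))
  cc <- tabulate_trios(ds, "snp001")
  case <- rowSums(cc$counts)
  ctrl <- rowSums(cc$control)
  chi <- suppressWarnings(chisq.test(cbind(case, ctrl)))
  expect_gt(chi$p.value, 0.01)
})

test_that("de novo injection respects its rate and is Mendelian-inconsistent", {
  ds <- simulate_trios(sim_config(n_case_exposed = 5, n_case_unexposed = 5,
                                  n_control_trios = 0,
                                  n_variants = 30, seed = suite_seed(17)))
  same <- inject_denovo(ds, 0)
  expect_identical(same$geno, ds$geno)

  set.seed(suite_seed(18))
  all10 <- inject_denovo(ds, 1)
  expect_equal(nrow(all10$truth$denovo), 10L)
  for (i in seq_len(10)) {
    fid <- all10$truth$denovo$fid[i]
    v <- all10$truth$denovo$variant[i]
    fam <- all10$families[all10$families$fid == fid, ]
    expect_equal(mendelian_check(all10$geno[v, fam$mother],
                                 all10$geno[v, fam$father],
                                 all10$geno[v, fam$child]), "inconsistent")
  }
})

test_that("mean injected de novo count follows the binomial mean", {
  ds <- simulate_trios(sim_config(n_case_exposed = 183, n_case_unexposed = 182,
                                  n_control_trios = 0, n_variants = 30,
                                  seed = suite_seed(19)))
  set.seed(suite_seed(20))
  counts <- replicate(200, nrow(inject_denovo(ds, 0.03)$truth$denovo))
  # 365 trios at rate 0.03: mean 10.95; MC SE of the mean over 200 sims
  mc_se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 365 * 0.03), 4 * mc_se)
})

test_that("per-call missingness hits the configured rate; zero rates are identity", {
  ds <- simulate_trios(sim_config(n_case_exposed = 500, n_case_unexposed = 500,
                                  n_variants = 2, seed = suite_seed(21)))
  same <- inject_missingness_and_errors(ds)
  expect_identical(same$geno, ds$geno)
  set.seed(suite_seed(22))
  out <- inject_missingness_and_errors(ds, missing_rates = c(mother = 0, father = 0, child = 0.3))
  kids <- ds$families$child
  rate <- mean(is.na(out$geno[, kids]))
  n <- length(out$geno[, kids])
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_identical(out$geno[, ds$families$mother], ds$geno[, ds$families$mother])
})

test_that("rare-region simulation is deterministic and null when non-causal", {
  cfg <- rare_sim_config(seed = suite_seed(23))
  expect_identical(simulate_rare_region(cfg)$child,
                   simulate_rare_region(cfg)$child)
  # null: transmissions from het parents are Bin(., 1/2)
  r <- simulate_rare_region(rare_sim_config(n_families = 2000,
                                            seed = suite_seed(24)))
  tc <- folatrio:::transmission_counts(r)
  tot <- tc$t + tc$nt
  expect_lt(abs(tc$t / tot - 0.5), 3 * sqrt(0.25 / tot))
})

test_that("causal architecture drives the expected burden/kernel contrast", {
  set.seed(suite_seed(25))
  zs_same <- zs_mixed <- q_mixed <- q_null <- numeric(200)
  for (i in 1:200) {
    s1 <- simulate_rare_region(rare_sim_config(causal_fraction = 1,
                                               effect_direction = "same",
                                               seed = sample.int(2^30, 1)))
    s2 <- simulate_rare_region(rare_sim_config(causal_fraction = 1,
                                               effect_direction = "mixed",
                                               seed = sample.int(2^30, 1)))
    s0 <- simulate_rare_region(rare_sim_config(seed = sample.int(2^30, 1)))
    zs_same[i] <- burden_tdt(maf_filter(s1))$statistic
    zs_mixed[i] <- burden_tdt(maf_filter(s2))$statistic
    q_mixed[i] <- kernel_test(maf_filter(s2), permute = 0)$statistic
    q_null[i] <- kernel_test(maf_filter(s0), permute = 0)$statistic
  }
  expect_gt(mean(zs_same), 0)
  expect_gt(t.test(zs_same)$statistic, 5)          # strongly positive
  expect_lt(abs(mean(zs_mixed)) , 3 * sd(zs_mixed) / sqrt(200))  # centred
  expect_gt(mean(q_mixed), mean(q_null))           # kernel sees mixed effects
})
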