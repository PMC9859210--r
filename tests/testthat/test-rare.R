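# Region-based rare-variant tests: MAF filter, transmission burden,
# family-based kernel score test, and the region scan.

test_that("MAF filter is strict at the threshold and counts from founders", {
  # 10 families; variant 1 at founder MAF exactly 0.05 (2/40 alleles
  # in parents), variant 2 at 0.025, variant 3 common (0.25)
  m <- cbind(c(1, rep(0, 9)), c(1, rep(0, 9)), c(rep(1, 5), rep(0, 5)))
  f <- cbind(c(1, rep(0, 9)), rep(0, 10), c(rep(1, 5), rep(0, 5)))
  c <- m * 0
  reg <- region_from_matrices(m, f, c)
  out <- maf_filter(reg, 0.05)
  expect_equal(colnames(out$child), "rv002")   # 0.05 removed (strict <)
  expect_equal(attr(out, "n_removed"), 2)
  # all-rare region is unchanged
  out2 <- maf_filter(reg, 0.5)
  expect_equal(ncol(out2$child), 3)
  # nothing retained -> untestable flag
  out3 <- maf_filter(reg, 0.01)
  expect_true(attr(out3, "untestable"))

  # mixed 10-variant panel with 3 common: 7 retained
  set.seed(suite_seed(70))
  mm <- sapply(c(rep(0.01, 7), rep(0.3, 3)), function(q) rbinom(200, 2, q))
  ff <- sapply(c(rep(0.01, 7), rep(0.3, 3)), function(q) rbinom(200, 2, q))
  reg2 <- region_from_matrices(mm, ff, mm * 0)
  expect_equal(ncol(maf_filter(reg2, 0.05)$child), 7)
})

test_that("burden statistic and exact p follow the transmission counts", {
  # 10 families, one rare variant, one het mother each; 8 transmit
  m <- matrix(1, 10, 1); f <- matrix(0, 10, 1)
  c <- matrix(c(rep(1, 8), 0, 0), 10, 1)
  res <- burden_tdt(region_from_matrices(m, f, c))
  expect_equal(res$t, 8); expect_equal(res$nt, 2)
  expect_equal(res$statistic, (8 - 2) / sqrt(10))
  expect_equal(res$p, 0.109375)   # 2 * (45 + 10 + 1) / 1024

  # balanced transmissions: z = 0, p = 1
  cb <- matrix(c(rep(1, 5), rep(0, 5)), 10, 1)
  resb <- burden_tdt(region_from_matrices(m, f, cb))
  expect_equal(resb$statistic, 0)
  expect_equal(resb$p, 1)

  # no informative transmissions -> untestable
  res0 <- burden_tdt(region_from_matrices(f, f, f))
  expect_true(res0$untestable)
})

test_that("exact burden p matches full enumeration for small counts", {
  enum_p <- function(t, tot) {
    probs <- dbinom(0:tot, tot, 0.5)
    sum(probs[probs <= probs[t + 1] * (1 + 1e-7)])
  }
  for (tot in c(4, 7, 12)) for (t in 0:tot) {
    m <- matrix(1, tot, 1); f <- matrix(0, tot, 1)
    c <- matrix(c(rep(1, t), rep(0, tot - t)), tot, 1)
    expect_equal(burden_tdt(region_from_matrices(m, f, c))$p,
                 enum_p(t, tot), tolerance = 1e-12)
  }
})

test_that("burden statistic is antisymmetric under a global transmission flip", {
  set.seed(suite_seed(71))
  r <- maf_filter(simulate_rare_region(rare_sim_config(causal_fraction = 0.5,
                                                       seed = suite_seed(72))))
  flip <- r
  # flipping every het-parent transmission: c' = nhet - tr + hom part
  hom <- (r$mother == 2) + (r$father == 2)
  nhet <- (r$mother == 1) + (r$father == 1)
  flip$child <- nhet - (r$child - hom) + hom
  expect_equal(burden_tdt(flip)$statistic, -burden_tdt(r)$statistic)
})

test_that("kernel test handles the degenerate and one-cell cases exactly", {
  # both parents hom-ref everywhere: no informative family
  z <- matrix(0, 5, 2)
  res <- kernel_test(region_from_matrices(z, z, z), permute = 0)
  expect_true(res$untestable)

  # single family, single variant, parents (1, 0), child 1:
  # E[c] = 0.5, Var = 0.25, S = 0.5, Q = w^2 * 0.25
  m <- matrix(1, 1, 1); f <- matrix(0, 1, 1); c <- matrix(1, 1, 1)
  reg <- region_from_matrices(m, f, c)
  reg$variants$maf <- 0.02
  res1 <- kernel_test(reg, permute = 0)
  w <- dbeta(0.02, 1, 25)
  expect_equal(res1$statistic, w^2 * 0.25)
  expect_equal(res1$n_informative_families, 1)
})

test_that("Q is invariant to variant order and uninformative families", {
  r <- maf_filter(simulate_rare_region(rare_sim_config(seed = suite_seed(73))))
  perm <- sample(ncol(r$child))
  r2 <- r
  r2$mother <- r$mother[, perm]; r2$father <- r$father[, perm]
  r2$child <- r$child[, perm]; r2$variants <- r$variants[perm, ]
  expect_equal(kernel_test(r2, permute = 0)$statistic,
               kernel_test(r, permute = 0)$statistic)
  # append families with hom-ref parents everywhere
  pad <- function(x, v) rbind(x, matrix(v, 10, ncol(x),
                                        dimnames = list(paste0("z", 1:10),
                                                        colnames(x))))
  r3 <- r
  r3$mother <- pad(r$mother, 0); r3$father <- pad(r$father, 0)
  r3$child <- pad(r$child, 0)
  expect_equal(kernel_test(r3, permute = 0)$statistic,
               kernel_test(r, permute = 0)$statistic)
})

test_that("moment-matched p tracks the permutation p", {
  set.seed(suite_seed(74))
  for (i in 1:6) {
    r <- maf_filter(simulate_rare_region(
      rare_sim_config(causal_fraction = ifelse(i %% 2, 0, 0.3),
                      seed = sample.int(2^30, 1))))
    k <- kernel_test(r, permute = 10000)
    se <- sqrt(k$p_permutation * (1 - k$p_permutation) / 10000)
    expect_lt(abs(k$p_moment - k$p_permutation), max(3 * se, 5e-4))
  }
})

test_that("null p-values of both tests are approximately uniform", {
  set.seed(suite_seed(75))
  n_rep <- 400
  pb <- pk <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    r <- maf_filter(simulate_rare_region(
      rare_sim_config(seed = sample.int(2^30, 1))))
    pb[i] <- burden_tdt(r)$p
    pk[i] <- kernel_test(r, permute = 0)$p
  }
  expect_gt(suppressWarnings(ks.test(pb, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(pk, "punif"))$p.value, 0.01)
})

test_that("region scan applies the Bonferroni threshold across regions", {
  set.seed(suite_seed(76))
  regions <- lapply(1:13, function(i)
    simulate_rare_region(rare_sim_config(seed = sample.int(2^30, 1))))
  names(regions) <- paste0("gene", 1:13)
  tab <- region_scan(regions, rare_test_config(n_permutations = 2000))
  expect_equal(nrow(tab), 13)
  expect_equal(round(tab$bonferroni_alpha[1], 4), 0.0038)
  # null regions: at most 1 significant
  expect_lte(sum(tab$kernel_significant, na.rm = TRUE), 1)
  expect_lte(sum(tab$burden_significant, na.rm = TRUE), 1)
})

test_that("bidirectional causal regions favour the kernel test over burden", {
  set.seed(suite_seed(77))
  kernel_first <- burden_first <- 0
  for (r in 1:60) {
    seeds <- sample.int(2^30, 13)
    regs <- c(list(simulate_rare_region(rare_sim_config(
      causal_fraction = 1, effect_direction = "mixed", seed = seeds[1]))),
      lapply(seeds[-1], function(s)
        simulate_rare_region(rare_sim_config(seed = s))))
    names(regs) <- paste0("g", 1:13)
    tab <- region_scan(regs, rare_test_config(n_permutations = 0))
    if (which.min(tab$kernel_p) == 1) kernel_first <- kernel_first + 1
    if (which.min(tab$burden_p) == 1) burden_first <- burden_first + 1
  }
  expect_gt(kernel_first, burden_first)
})
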