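test_that("fixed-S conditioning holds in every mode", {
  set.seed(61)
  for (mode in c("none", "free")) {
    ss <- simulate_sample(coal_config(9, 17, mode))
    expect_equal(ncol(ss$states), 17L)
    expect_equal(ss$S, 17L)
    # each site is segregating: both alleles observed
    expect_true(all(colSums(ss$states) >= 1 & colSums(ss$states) <= 8))
  }
  ssr <- simulate_sample(coal_config(8, 11, "rho", rho = 3, L = 100))
  expect_equal(ncol(ssr$states), 11L)
  expect_true(all(colSums(ssr$states) >= 1 & colSums(ssr$states) <= 7))
})

test_that("n = 2 samples always split 1|1 and give Rm = 0", {
  set.seed(62)
  ss <- simulate_sample(coal_config(2, 5, "none"))
  expect_true(all(colSums(ss$states) == 1))
  expect_equal(four_gamete_Rm(ss), 0L)
})

test_that("same seed gives bit-identical null distributions", {
  cfg <- coal_config(8, 10, "none", reps = 50, seed = 99)
  a <- null_distribution(cfg, four_gamete_Rm, observed = 1)
  b <- null_distribution(cfg, four_gamete_Rm, observed = 1)
  expect_identical(a$samples, b$samples)
  expect_identical(a$p_ge, b$p_ge)
})

test_that("empirical p-values honour the add-one correction at the extremes", {
  cfg <- coal_config(10, 15, "none", reps = 99, seed = 7)
  lo <- null_distribution(cfg, four_gamete_Rm, observed = -1)
  expect_equal(lo$p_ge, 1)          # observed below every simulated value
  hi <- null_distribution(cfg, four_gamete_Rm, observed = 1e9)
  expect_equal(hi$p_ge, 1 / 100)    # (0 + 1)/(reps + 1)
  expect_equal(hi$p_ge_raw, 0)
})

test_that("free recombination inflates mean pairwise r2 no more than the
           linkage-equilibrium level and dominates the Rm null", {
  set.seed(63)
  r2s <- replicate(60, {
    ss <- simulate_sample(coal_config(20, 30, "free"))
    zz_statistic(ss)$ZnS
  })
  expect_lt(mean(r2s), 0.12)        # ~1/(n-1) plus small-sample bias

  rm_free <- replicate(60, four_gamete_Rm(
    simulate_sample(coal_config(15, 25, "free"))))
  rm_none <- replicate(60, four_gamete_Rm(
    simulate_sample(coal_config(15, 25, "none"))))
  expect_gt(mean(rm_free), mean(rm_none))
})

test_that("rho = 0 ARG is distributed like the plain coalescent", {
  set.seed(64)
  rm_a <- replicate(150, four_gamete_Rm(
    simulate_sample(coal_config(10, 15, "rho", rho = 0, L = 100))))
  rm_b <- replicate(150, four_gamete_Rm(
    simulate_sample(coal_config(10, 15, "none"))))
  ks <- suppressWarnings(ks.test(rm_a, rm_b))
  expect_gt(ks$p.value, 0.01)
})

test_that("positive rho produces more minimum recombination events", {
  set.seed(65)
  rm_rho <- replicate(40, four_gamete_Rm(
    simulate_sample(coal_config(12, 20, "rho", rho = 20, L = 200))))
  rm_none <- replicate(40, four_gamete_Rm(
    simulate_sample(coal_config(12, 20, "none"))))
  expect_gt(mean(rm_rho), mean(rm_none) + 0.5)
})
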