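test_that("ENC hits its theoretical limits", {
  gc <- genetic_code()
  fams <- dupsel:::.codon_families(gc)
  # one codon per amino acid, several observations each -> ENC = 20
  one_per_aa <- unlist(lapply(fams, function(f) rep(f[1], 5)))
  expect_equal(enc(one_per_aa), 20)
  # exactly uniform synonymous usage -> clamped at 61
  uniform <- unlist(lapply(fams, function(f) rep(f, 10)))
  expect_equal(enc(uniform), 61)
  # permutation invariance
  set.seed(91)
  shuf <- sample(uniform)
  expect_equal(enc(shuf), enc(uniform))
})

test_that("random uniform codon draws land in the near-61 band", {
  set.seed(92)
  v <- enc(rand_sense_codons(5000))
  expect_gt(v, 55); expect_lte(v, 61)
})

test_that("the ENC-GC3 expectation curve matches its closed form", {
  expect_equal(enc_expected(0.5), 2 + 0.5 + 29 / 0.5)   # 60.5
  s <- 0.3
  expect_equal(enc_expected(s), 2 + s + 29 / (s^2 + (1 - s)^2))
  # unimodal with the maximum at s = 0.5 on a grid
  grid <- seq(0.05, 0.95, by = 0.01)
  vals <- enc_expected(grid)
  expect_equal(grid[which.max(vals)], 0.5)
  expect_true(all(diff(vals[grid <= 0.5]) > 0))
  expect_true(all(diff(vals[grid >= 0.5]) < 0))
})

test_that("CBI matches hand computation and responds to optimal counts", {
  # two-codon family only (Phe), 75% optimal over 1000 codons
  seqs <- c(rep("TTT", 750), rep("TTC", 250))
  expect_equal(cbi(seqs, optimal_codons = "TTT"), 0.5)
  expect_equal(cbi(rep("TTT", 100), optimal_codons = "TTT"), 1)
  # uniform usage -> ~0
  set.seed(93)
  unif <- sample(c("TTT", "TTC"), 4000, replace = TRUE)
  expect_lt(abs(cbi(unif, optimal_codons = "TTT")), 0.05)
  # strictly increasing in the optimal count with totals fixed
  v1 <- cbi(c(rep("TTT", 600), rep("TTC", 400)), "TTT")
  v2 <- cbi(c(rep("TTT", 700), rep("TTC", 300)), "TTT")
  expect_gt(v2, v1)
})

test_that("modal-codon inference is deterministic with alphabetical ties", {
  opt <- infer_optimal_codons(c("TTTTTC"))   # tie between TTT and TTC
  expect_equal(unname(opt[genetic_code()$aa[opt] == "F"]), "TTC")
})

test_that("group comparison handles identity, separation and conventions", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, t.test(c(1, 2, 3), c(1, 2, 3))$p.value)
  shift <- compare_groups(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p, 0.01)
  degen <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(degen$t, 0); expect_equal(degen$p, 1)
})

test_that("codon_usage produces per-sequence and grouped tables", {
  fx <- codon_fixture(seed = 94, n_codons = 120)
  grp <- setNames(rep(c("g1", "g2"), length.out = nrow(fx$ca$aln)),
                  rownames(fx$ca$aln))
  cu <- codon_usage(fx$ca, groups = grp)
  expect_equal(nrow(cu$table), nrow(fx$ca$aln))
  expect_true(all(cu$table$ENC >= 20 & cu$table$ENC <= 61, na.rm = TRUE))
  expect_true(all(abs(cu$table$CBI) <= 1, na.rm = TRUE))
  expect_true(all(cu$table$GC3 >= 0 & cu$table$GC3 <= 1))
  expect_equal(nrow(cu$group_summary), 2L)
  expect_false(is.null(cu$tests))
})
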