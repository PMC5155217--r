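test_that("segregating sites classifies biallelic and multiallelic sites", {
  a <- aln(c("AAT", "AAA", "AAT"))
  ss <- segregating_sites(a)
  expect_equal(ss$S, 1L)
  expect_equal(ss$positions, 3L)

  expect_equal(segregating_sites(aln(rep("ACGT", 4)))$S, 0L)

  b <- aln(c("AC", "AG", "AT"))
  ssb <- segregating_sites(b)
  expect_equal(ssb$multiallelic_positions, 2L)
  expect_equal(length(ssb$positions), 0L)
  expect_equal(ssb$S, 1L)   # multiallelic still counts toward S

  expect_error(segregating_sites(aln("ACGT")), "input-error")
})

test_that("pi and Watterson's theta match closed forms and brute force", {
  expect_equal(nucleotide_diversity(aln(c("AAAA", "AAAT")))$per_gene, 1)
  # n=4, S=3: theta = 3 / (1 + 1/2 + 1/3)
  a <- aln(c("AAAT", "AATA", "ATAA", "TAAA"))
  ss <- segregating_sites(a)
  expect_equal(ss$S, 4L)
  ss$S <- 3L
  expect_equal(watterson_theta(ss), 3 / (1 + 1 / 2 + 1 / 3),
               tolerance = 1e-4)

  set.seed(7)
  for (i in 1:5) {
    x <- rand_aln(6, 100, miss = if (i > 3) 0.05 else 0)
    expect_equal(nucleotide_diversity(x)$per_gene, brute_pi(x))
  }
})

test_that("Tajima's D matches an independent constants recomputation", {
  # toy: 4 haplotypes 0000, 0011, 1100, 1111 over 4 segregating sites
  a <- aln(c("AAAA", "AATT", "TTAA", "TTTT"))
  got <- tajimas_d(a)
  # spreadsheet-style oracle with Tajima's constants written out afresh
  n <- 4; S <- 4
  k <- c(2, 4, 2, 2, 4, 2)           # all pairwise differences
  pi <- mean(k)
  a1 <- 1 + 1 / 2 + 1 / 3
  a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  D_oracle <- (pi - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
  expect_equal(got$D, D_oracle, tolerance = 1e-12)
  expect_equal(got$pi, pi)

  # S = 0 -> undefined, reported as missing
  expect_true(is.na(tajimas_d(aln(rep("ACGTACGT", 4)))$D))
  expect_error(tajimas_d(aln(c("AA", "AT"))), "input-error")
})

test_that("Hudson's R is monotone, definitionally consistent, and handles
           degenerate input", {
  set.seed(21)
  ss <- simulate_sample(coal_config(12, 25, "none"))
  x <- segsites_to_aln(ss)
  h <- hudson_R(x)
  expect_equal(h$R_adjacent * ncol(x), h$R_gene)

  expect_true(is.na(hudson_R(aln(rep("ACGT", 5)))$R_gene))

  # monotonicity: the expectation equation is decreasing in C, so a sample
  # with smaller variance must give a larger estimate
  set.seed(22)
  x_free <- segsites_to_aln(simulate_sample(coal_config(15, 30, "free")))
  x_link <- segsites_to_aln(simulate_sample(coal_config(15, 30, "none")))
  h_free <- hudson_R(x_free); h_link <- hudson_R(x_link)
  expect_gt(h_free$R_gene, h_link$R_gene)
})

test_that("Hudson's R recovers the simulated recombination rate to within a
           broad band", {
  set.seed(23)
  est <- replicate(30, {
    ss <- simulate_sample(coal_config(20, 40, "rho", rho = 10, L = 500))
    hudson_R(segsites_to_aln(ss))$R_gene
  })
  expect_gt(median(est), 2)
  expect_lt(median(est), 50)
})

test_that("four-gamete Rm equals exhaustive interval-cover search", {
  # two sites with all four gametes
  a <- aln(c("AA", "AT", "TA", "TT"))
  expect_equal(four_gamete_Rm(segregating_sites(a)), 1L)
  # S <= 1
  expect_equal(four_gamete_Rm(segregating_sites(aln(c("AA", "AA", "AT")))),
               0L)
  set.seed(31)
  for (i in 1:50) {
    ss <- simulate_sample(coal_config(8, sample(3:8, 1), "free"))
    expect_equal(four_gamete_Rm(ss), brute_rm(ss))
  }
})

test_that("Za/ZnS/ZZ match brute-force r2 recomputation", {
  set.seed(41)
  for (i in 1:10) {
    ss <- simulate_sample(coal_config(20, 12, "free"))
    z <- zz_statistic(ss)
    bz <- brute_zz(ss)
    expect_equal(z$Za, bz$Za, tolerance = 1e-12)
    expect_equal(z$ZnS, bz$ZnS, tolerance = 1e-12)
    expect_equal(z$ZZ, z$Za - z$ZnS)
    expect_true(z$ZZ >= -1 && z$ZZ <= 1)
  }
  # S = 2: Za == ZnS
  ss2 <- simulate_sample(coal_config(10, 2, "none"))
  z2 <- zz_statistic(ss2)
  expect_equal(z2$ZZ, 0)
  # perfect LD: duplicated column
  a <- aln(c("AATT", "AATT", "TTAA", "TTAA"))
  expect_equal(zz_statistic(segregating_sites(a))$ZZ, 0)
})

test_that("pi and theta are invariant to row and site permutations", {
  set.seed(51)
  x <- rand_aln(8, 60)
  m <- unclass(x)
  x_rows <- aln(m[sample(nrow(m)), ])
  x_sites <- aln(m[, sample(ncol(m))])
  expect_equal(nucleotide_diversity(x)$per_gene,
               nucleotide_diversity(x_rows)$per_gene)
  expect_equal(nucleotide_diversity(x)$per_gene,
               nucleotide_diversity(x_sites)$per_gene)
  expect_equal(watterson_theta(segregating_sites(x)),
               watterson_theta(segregating_sites(x_sites)))
  # Rm and Za depend on site order but not row order
  ss <- segregating_sites(x)
  ssr <- segregating_sites(x_rows)
  expect_equal(four_gamete_Rm(ss), four_gamete_Rm(ssr))
  expect_equal(zz_statistic(ss)$Za, zz_statistic(ssr)$Za)
})
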