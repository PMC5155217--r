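test_that("tree simulation is seed-deterministic and delivers n tips", {
  t1 <- simulate_tree("yule", 7, birth = 1, seed = 11)
  t2 <- simulate_tree("yule", 7, birth = 1, seed = 11)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_equal(length(t1$tip.label), 7L)
  expect_true(ape::is.ultrametric(t1, tol = 1e-6))

  tb <- simulate_tree("birth-death", 6, birth = 1, death = 0.3, seed = 12)
  expect_equal(length(tb$tip.label), 6L)
  expect_true(ape::is.ultrametric(tb, tol = 1e-6))
})

test_that("yule internode intervals match their exponential expectations", {
  set.seed(13)
  bt <- replicate(800, {
    tr <- simulate_tree("yule", 3, birth = 1)
    sort(ape::branching.times(tr), decreasing = TRUE)
  })
  g2 <- bt[1, ] - bt[2, ]    # duration with 2 lineages
  g3 <- bt[2, ]              # duration with 3 lineages
  expect_equal(mean(g2), 1 / 2, tolerance = 0.1)
  expect_equal(mean(g3), 1 / 3, tolerance = 0.1)
})

test_that("duplication gene trees have the stated structure", {
  trb <- simulate_duplication_gene_tree(
    dup_scenario(4, "before-speciation"), seed = 14)
  expect_setequal(trb$tip.label,
                  c(paste0("sp", 1:4, "_dup1"), paste0("sp", 1:4, "_dup2")))
  expect_true(ape::is.monophyletic(trb, paste0("sp", 1:4, "_dup1")))
  expect_true(ape::is.monophyletic(trb, paste0("sp", 1:4, "_dup2")))

  tra <- simulate_duplication_gene_tree(
    dup_scenario(4, "after-speciation"), seed = 15)
  for (s in paste0("sp", 1:4))
    expect_true(ape::is.monophyletic(tra, paste0(s, c("_dup1", "_dup2"))))
})

test_that("codon simulation honours omega = 0, zero branch lengths, and
           reconciles realized counts with sequence divergence", {
  tr <- read_newick(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);")
  s0 <- simulate_codon_alignment(tr, 100, omega = 0, seed = 16)
  expect_equal(sum(s0$record$n_nonsyn), 0L)
  expect_gt(sum(s0$record$n_syn), 0L)

  trz <- tr; trz$edge.length[] <- 0
  sz <- simulate_codon_alignment(trz, 50, omega = 1, seed = 17)
  m <- unclass(sz$ca$aln)
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1)))

  # at low rates, realized event counts match pairwise Hamming distances
  trl <- read_newick(text = "(a:0.02,b:0.02);")
  sl <- simulate_codon_alignment(trl, 400, omega = 1, seed = 18)
  events <- sum(sl$record$n_syn + sl$record$n_nonsyn)
  ham <- sum(unclass(sl$ca$aln)[1, ] != unclass(sl$ca$aln)[2, ])
  expect_lte(ham, events)
  expect_gte(ham, 0.8 * events)   # few multiple hits at this depth

  # determinism
  sa <- simulate_codon_alignment(tr, 30, omega = 0.5, seed = 19)
  sb <- simulate_codon_alignment(tr, 30, omega = 0.5, seed = 19)
  expect_identical(unclass(sa$ca$aln), unclass(sb$ca$aln))
})

test_that("omega = 1 simulation yields NG86 pN/pS near one", {
  tr <- read_newick(text = "(a:0.4,b:0.4);")
  set.seed(20)
  ratios <- replicate(12, {
    sim <- simulate_codon_alignment(tr, 500, omega = 1)
    cods <- dupsel:::codon_strings(sim$ca)
    ng <- ng86_counts(cods[1, ], cods[2, ])
    ng$pN / ng$pS
  })
  expect_gt(median(ratios), 0.85)
  expect_lt(median(ratios), 1.15)
})

test_that("radical-bias generator partitions sites exactly and controls the
           divergent fraction", {
  sim <- simulate_radical_bias(200, 0.25, 4, noise_rate = 0, seed = 21)
  expect_equal(sum(sim$truth), 50L)
  # all truth sites have ancestors in different charge classes
  ch <- dupsel:::.aa_charge
  expect_true(all(ch[sim$anc1[sim$truth]] != ch[sim$anc2[sim$truth]]))
  expect_true(all(sim$anc1[!sim$truth] == sim$anc2[!sim$truth]))
  expect_equal(nrow(sim$aln), 8L)
})
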