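test_that("distance methods agree with hand values and ape on basics", {
  a <- aln(c(x = "AAAA", y = "AAAA"))
  for (m in c("p", "JC69", "K2P"))
    expect_equal(unclass(distance_matrix(a, m))["x", "y"], 0)

  b <- aln(c(x = "AAAATTTT", y = "AAAATTTC"))
  expect_equal(unclass(distance_matrix(b, "p"))["x", "y"], 1 / 8)
  # cross-check JC69/K2P against ape::dist.dna
  set.seed(71)
  r <- rand_aln(4, 300)
  bin <- ape::as.DNAbin(unclass(r))
  for (pair in list(c("JC69", "JC69"), c("K2P", "K80"))) {
    mine <- unclass(suppressWarnings(distance_matrix(r, pair[1])))
    theirs <- as.matrix(ape::dist.dna(bin, model = pair[2]))
    theirs <- theirs[rownames(mine), colnames(mine)]
    theirs[!is.finite(theirs)] <- NA    # ape marks saturation Inf/NaN
    expect_equal(mine, theirs, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("NG distances separate synonymous from nonsynonymous divergence", {
  ca <- to_codon_alignment(aln(c(x = "TTTAAA", y = "TTCAAA")))
  expect_equal(unclass(distance_matrix(ca, "NG-nonsyn"))["x", "y"], 0)
  expect_gt(unclass(distance_matrix(ca, "NG-syn"))["x", "y"], 0)
})

test_that("NJ recovers additive trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1):1)
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 3
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 4
  D["C", "D"] <- D["D", "C"] <- 4
  tr <- neighbor_joining(D)
  # topology: AB | CD split
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  # path distances reproduce the input matrix
  got <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(got, D, tolerance = 1e-9)

  set.seed(72)
  # random additive 5-taxon matrix from a random tree
  tru <- ape::rtree(5)
  D5 <- ape::cophenetic.phylo(tru)
  tr5 <- neighbor_joining(D5)
  expect_equal(ape::cophenetic.phylo(tr5)[rownames(D5), colnames(D5)],
               D5, tolerance = 1e-9)

  expect_error(neighbor_joining(D[1:2, 1:2]), "input-error")
  expect_true(all(tr$edge.length >= 0))
})

test_that("gamma matches the closed form, ape, and is scale invariant", {
  # n = 3 with g2 = g3 = 1: hand evaluation of the closed form
  tr3 <- read_newick(text = "((A:1,B:1):1,C:2);")
  g <- gamma_statistic(tr3)
  T_tot <- 2 * 1 + 3 * 1
  num <- (1 / 1) * (2 * 1) - T_tot / 2
  expect_equal(g$gamma, num / (T_tot * sqrt(1 / 12)), tolerance = 1e-10)
  # cross-check against the independent implementation in ape
  expect_equal(g$gamma, ape::gammaStat(tr3), tolerance = 1e-10)

  set.seed(73)
  tr <- simulate_tree("yule", 12, birth = 1)
  expect_equal(gamma_statistic(tr)$gamma, ape::gammaStat(tr),
               tolerance = 1e-8)
  # linear rescaling leaves gamma unchanged
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 7.3
  expect_equal(gamma_statistic(tr2)$gamma, gamma_statistic(tr)$gamma,
               tolerance = 1e-10)

  expect_error(gamma_statistic(read_newick(text = "(A:1,B:1);")),
               "input-error")
})

test_that("comb-like trees with recent splits give large positive gamma", {
  # root split at depth 0, the other 18 splits compressed in the last 5%
  n <- 20
  d <- c(0, seq(0.95, 0.999, length.out = n - 2))
  s <- sprintf("(t%d:%.6f,t%d:%.6f)", n - 1, 1 - d[n - 1], n, 1 - d[n - 1])
  for (k in (n - 2):1)
    s <- sprintf("(t%d:%.6f,%s:%.6f)", k, 1 - d[k], s, d[k + 1] - d[k])
  tr <- read_newick(text = paste0(s, ";"))
  expect_true(ape::is.ultrametric(tr, tol = 1e-4))
  expect_gt(gamma_statistic(tr)$gamma, 2)
})

test_that("LTT curves count lineages correctly and ignore ladderization", {
  tr <- read_newick(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  lt <- ltt_curve(tr)
  expect_equal(lt$lineages[1], 2L)
  expect_equal(lt$lineages[nrow(lt)], 4L)
  expect_equal(lt$time[lt$lineages == 4][1], 0.5)

  set.seed(74)
  tr2 <- simulate_tree("yule", 10, birth = 1)
  lad <- ape::ladderize(tr2)
  expect_equal(ltt_curve(tr2)$time, ltt_curve(lad)$time, tolerance = 1e-12)
  expect_equal(ltt_curve(tr2)$lineages, ltt_curve(lad)$lineages)
})

test_that("make_ultrametric yields an ultrametric rooted tree", {
  set.seed(75)
  tr <- ape::rtree(8)
  ut <- make_ultrametric(tr)
  expect_true(ape::is.rooted(ut))
  expect_true(ape::is.ultrametric(ut, tol = 1e-6))
})
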