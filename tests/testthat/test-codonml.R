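test_that("NG86 counting matches trivial cases and the pathway oracle", {
  same <- ng86_counts("TTTAAA", "TTTAAA")
  expect_equal(same$Sd, 0); expect_equal(same$Nd, 0)
  expect_equal(same$dS, 0); expect_equal(same$dN, 0)

  phe <- ng86_counts("TTT", "TTC")       # synonymous Phe
  expect_equal(phe$Sd, 1); expect_equal(phe$Nd, 0)

  set.seed(81)
  for (i in 1:8) {
    a <- rand_sense_codons(60)
    b <- rand_sense_codons(60)
    got <- ng86_counts(a, b)
    ora <- ng86_oracle(a, b)
    expect_equal(got$S_sites, ora$S_sites, tolerance = 1e-10)
    expect_equal(got$Sd, ora$Sd, tolerance = 1e-10)
    expect_equal(got$Nd, ora$Nd, tolerance = 1e-10)
  }
  # omega flagged infinite when dS = 0 but dN > 0
  inf <- ng86_counts("AAA", "GAA")       # K -> E, nonsynonymous only
  expect_true(inf$omega_infinite)
  expect_equal(inf$omega, Inf)
})

test_that("codon rate matrix is a proper scaled reversible generator", {
  cs <- dupsel:::codon_setup()
  pi <- as.numeric(dupsel:::codon_freqs(
    to_codon_alignment(aln(c(a = "ATGAAATTT", b = "ATGAAGTTC"))), "F3x4"))
  eg <- dupsel:::codon_eigen(2, 0.4, pi, cs)
  Q <- eg$Q
  expect_equal(rowSums(Q), rep(0, 61), tolerance = 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)   # mean rate 1
  expect_equal(as.numeric(pi %*% Q), rep(0, 61), tolerance = 1e-12)
  P <- dupsel:::codon_P(eg, 0.37)
  expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-8)
  expect_true(all(P >= 0))
  expect_equal(as.numeric(pi %*% P), pi, tolerance = 1e-10)  # stationarity
})

test_that("site likelihoods equal the pairwise oracle on two sequences and
           behave at limits", {
  tr2 <- read_newick(text = "(a:0.2,b:0.3);")
  sim <- simulate_codon_alignment(tr2, 120, kappa = 2, omega = 0.5,
                                  seed = 82)
  pi <- rep(1 / 61, 61)
  st <- dupsel:::codon_states(sim$ca)
  eg <- dupsel:::codon_eigen(2, 0.5, pi, dupsel:::codon_setup())
  P <- dupsel:::codon_P(eg, 0.5)
  oracle <- sum(log(pi[st[1, ]] * P[cbind(st[1, ], st[2, ])]))
  mine <- site_log_likelihoods(sim$ca, tr2, kappa = 2, omega = 0.5,
                               freqs = pi)
  expect_equal(mine$lnL, oracle, tolerance = 1e-8)
  expect_equal(sum(mine$site_lnL), mine$lnL, tolerance = 1e-8)

  # identical sequences on vanishing branches -> sum log pi
  a2 <- aln(c(x = strrep("ATG", 40), y = strrep("ATG", 40)))
  ca2 <- to_codon_alignment(a2)
  tr0 <- read_newick(text = "(x:0.00000001,y:0.00000001);")
  v <- site_log_likelihoods(ca2, tr0, kappa = 2, omega = 1, freqs = pi)$lnL
  expect_equal(v, 40 * log(1 / 61), tolerance = 1e-4)

  # class-proportion rescaling leaves the likelihood unchanged
  fx <- codon_fixture(seed = 83, n_codons = 60)
  cls1 <- list(list(prop = 0.6, w_bg = 0.2, w_fg = 0.2),
               list(prop = 0.4, w_bg = 1.5, w_fg = 1.5))
  cls2 <- lapply(cls1, function(c0) { c0$prop <- c0$prop * 2; c0 })
  l1 <- site_log_likelihoods(fx$ca, fx$tree, kappa = 2, classes = cls1)$lnL
  l2 <- site_log_likelihoods(fx$ca, fx$tree, kappa = 2, classes = cls2)$lnL
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("likelihood is invariant under re-rooting (reversibility)", {
  fx <- codon_fixture(seed = 84, n_codons = 80)
  tr <- fx$tree
  l0 <- site_log_likelihoods(fx$ca, tr, kappa = 2, omega = 0.4)$lnL
  ur <- ape::unroot(tr)
  l1 <- site_log_likelihoods(fx$ca, ur, kappa = 2, omega = 0.4)$lnL
  rr <- ape::root(ur, outgroup = tr$tip.label[1], resolve.root = TRUE)
  l2 <- site_log_likelihoods(fx$ca, rr, kappa = 2, omega = 0.4)$lnL
  expect_equal(l0, l1, tolerance = 1e-6)
  expect_equal(l1, l2, tolerance = 1e-6)
})

test_that("M0 recovers simulation parameters on a small instance", {
  fx <- codon_fixture(seed = 85, n_codons = 300, omega = 0.3)
  fit <- fit_model(fx$ca, fx$tree, "M0")
  expect_true(fit$converged)
  expect_gt(fit$mles$omega, 0.15)
  expect_lt(fit$mles$omega, 0.5)
  expect_equal(fit$np, nrow(fx$tree$edge) + 2L)
})

test_that("free-ratio model assigns elevated omega to the elevated branch", {
  tr <- read_newick(text = "((a:0.3,b:0.3):0.15,(c:0.3,d:0.3):0.15);")
  fg <- which(tr$edge[, 2] == match("a", tr$tip.label))
  cls <- list(list(prop = 1, w_bg = 0.1, w_fg = 4))
  sim <- simulate_codon_alignment(tr, 300, kappa = 2, classes = cls,
                                  fg_edges = fg, seed = 86)
  fit <- fit_model(sim$ca, tr, "free")
  expect_equal(length(fit$per_branch_omega), nrow(tr$edge))
  wa <- fit$per_branch_omega[fg]
  expect_gt(wa, max(fit$per_branch_omega[-fg]))
})

test_that("LRT arithmetic, boundary mixture and the optimizer-warning path", {
  r <- lrt(-100, -97.5, df = 1)
  expect_equal(r$two_delta_L, 5)
  expect_equal(r$p, pchisq(5, 1, lower.tail = FALSE))
  rm <- lrt(-100, -97.5, df = 1, boundary_mixture = TRUE)
  expect_equal(rm$p, 0.5 * pchisq(5, 1, lower.tail = FALSE))
  expect_equal(lrt(-50, -50)$two_delta_L, 0)
  expect_equal(lrt(-50, -50, boundary_mixture = TRUE)$p, 1)
  expect_warning(lrt(-50, -51), "optimizer-warning")
})

test_that("site posteriors sum to one and reduce to the prior at
           uninformative sites", {
  fx <- codon_fixture(seed = 87, n_codons = 100, omega = 0.3)
  m0 <- fit_model(fx$ca, fx$tree, "M0")
  f2 <- fit_model(fx$ca, m0$tree, "M2a", restarts = 1)
  sp <- site_posteriors(f2)
  expect_true(all(sp$p_positive >= 0 & sp$p_positive <= 1))
  cp <- attr(sp, "class_posterior")
  expect_equal(rowSums(cp), rep(1, nrow(cp)), tolerance = 1e-8)

  # alignment column identical across taxa -> posterior equals the prior
  onecol <- to_codon_alignment(
    aln(setNames(rep(strrep("ATG", 10), 5), fx$tree$tip.label)))
  cls <- dupsel:::.template("M2a")$classes(f2$par, integer(0))
  ll <- dupsel:::codon_site_lik(
    dupsel:::codon_patterns(dupsel:::codon_states(onecol)),
    m0$tree, f2$mles$kappa, f2$pi, cls, integer(0),
    dupsel:::codon_setup())
  props <- vapply(cls, `[[`, 0, "prop")
  lik <- exp(ll[1, ] - max(ll[1, ]))
  post <- props * lik / sum(props * lik)
  # invariant site: every class explains it almost equally, posterior ~ prior
  expect_equal(post, props, tolerance = 0.05)

  expect_error(site_posteriors(m0), "input-error")
})

test_that("KH/SH behave on identical topologies and order correctly", {
  fx <- codon_fixture(seed = 88, n_codons = 100)
  trees <- list(fx$tree, fx$tree)
  res <- kh_sh_tests(fx$ca, trees, n_boot = 500, seed = 1)
  expect_equal(res$p_KH, c(1, 1))
  expect_equal(res$delta, c(0, 0))

  # two genuinely different topologies: SH >= KH for the worse one
  alt <- fx$tree
  alt$tip.label <- alt$tip.label[c(2, 1, 3, 4, 5)]
  res2 <- kh_sh_tests(fx$ca, list(fx$tree, alt), n_boot = 500, seed = 2)
  worse <- which(!res2$best)
  expect_true(all(res2$p_SH[worse] >= res2$p_KH[worse] - 1e-9))
  expect_error(kh_sh_tests(fx$ca, list(fx$tree)), "input-error")
})
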