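test_that("radical/conserved classification follows the property partition", {
  expect_equal(classify_change("K", "R"), "conserved")   # both positive
  expect_equal(classify_change("D", "H"), "radical")     # negative -> positive
  expect_equal(classify_change("I", "L"), "conserved")   # both hydrophobic
  expect_equal(classify_change("F", "S"), "radical")     # hydropathy flip
  expect_true(is.na(classify_change("X", "A")))
  # symmetry over all standard pairs
  aa <- dupsel:::.AA20
  for (i in 1:19) for (j in (i + 1):20)
    expect_equal(classify_change(aa[i], aa[j]), classify_change(aa[j], aa[i]))
})

test_that("ancestral reconstruction is exact on easy sites", {
  # invariant site and a single deviant tip on a star-ish clade
  m <- rbind(s1 = c("A", "K"), s2 = c("A", "K"), s3 = c("A", "K"),
             s4 = c("A", "R"))
  x <- aln(m, type = "protein")
  tr <- read_newick(text = "((s1:0.1,s2:0.1):0.05,(s3:0.1,s4:0.1):0.05);")
  r <- ancestral_states(x, tree = tr)
  expect_equal(unname(r$ancestral), c("A", "K"))
  expect_equal(r$changes[1], 0L)
  expect_gte(r$changes[2], 1L)
})

test_that("ancestral reconstruction has high site accuracy at low rates", {
  set.seed(95)
  acc <- replicate(5, {
    sim <- simulate_radical_bias(n_sites = 150, divergent_fraction = 0,
                                 n_per_clade = 5, noise_rate = 0.04)
    r <- ancestral_states(
      aln(unclass(sim$aln)[sim$tips1, ], type = "protein"))
    mean(r$ancestral == sim$anc1, na.rm = TRUE)
  })
  expect_gt(mean(acc), 0.9)
})

test_that("type-II statistic is exactly zero for identical ancestors and
           detects forced radical divergence", {
  set.seed(96)
  null_sim <- simulate_radical_bias(255, 0, 5, noise_rate = 0)
  pair <- cluster_pair(null_sim$aln, null_sim$tips1, null_sim$tips2)
  t2 <- gu_type2(pair, boot = 50)
  expect_equal(t2$theta_II, 0)
  expect_equal(t2$R, 0L); expect_equal(t2$C, 0L)
  expect_equal(t2$N, 255L)

  div_sim <- simulate_radical_bias(255, 0.1, 5, noise_rate = 0.01,
                                   seed = 97)
  pair2 <- cluster_pair(div_sim$aln, div_sim$tips1, div_sim$tips2)
  t2b <- gu_type2(pair2, boot = 200, seed = 1)
  expect_gt(t2b$theta_II, 0.02)
  expect_gt(t2b$z, 2)
  expect_equal(t2b$z, t2b$theta_II / t2b$se)           # z by definition
  expect_equal(t2b$N + t2b$C + t2b$R,
               sum(!is.na(t2b$site_class)))
})

test_that("posterior ratio profile obeys the ratio/probability identity and
           ranks divergent sites highly", {
  div_sim <- simulate_radical_bias(255, 0.1, 5, noise_rate = 0.01,
                                   seed = 98)
  pair <- cluster_pair(div_sim$aln, div_sim$tips1, div_sim$tips2)
  t2 <- gu_type2(pair, boot = 100, seed = 2)
  prof <- site_posterior_profile(t2)
  expect_equal(prof$posterior, prof$ratio / (1 + prof$ratio))
  # ratio 4 <-> posterior 0.8 exactly
  expect_equal(4 / (1 + 4), 0.8)
  # invariant sites score far below forced-divergent sites
  expect_lt(max(prof$ratio[prof$class == "N"], na.rm = TRUE),
            min(prof$ratio[div_sim$truth & prof$class == "R"],
                na.rm = TRUE) + 1e-9)
  # AUC of ratio for truth recovery
  r <- rank(prof$ratio)
  auc <- (mean(r[div_sim$truth]) - (sum(div_sim$truth) + 1) / 2) /
    sum(!div_sim$truth)
  expect_gt(auc, 0.8)
})

test_that("type-I statistics are calibrated at the null and respond to
           rate switching", {
  set.seed(99)
  # null: same per-site rates in both clades (shared heterogeneity)
  mk_pair <- function(switch_frac, seed) {
    set.seed(seed)
    L <- 200
    base_rate <- rgamma(L, 0.8, 1) * 0.15
    rate2 <- base_rate
    if (switch_frac > 0) {
      idx <- sample.int(L, round(switch_frac * L))
      rate2[idx] <- sample(base_rate, length(idx))   # decorrelate
    }
    anc <- sample(dupsel:::.AA20, L, replace = TRUE)
    evolve <- function(rates) {
      m <- matrix(rep(anc, 5), nrow = 5, byrow = TRUE)
      for (i in 1:5) {
        hits <- which(runif(L) < rates)
        if (length(hits)) m[i, hits] <- vapply(m[i, hits], function(a)
          sample(setdiff(dupsel:::.AA20, a), 1), "")
      }
      m
    }
    m <- rbind(evolve(base_rate), evolve(rate2))
    rownames(m) <- c(paste0("a", 1:5), paste0("b", 1:5))
    cluster_pair(aln(m, type = "protein"), paste0("a", 1:5),
                 paste0("b", 1:5))
  }
  t_null <- gu_type1(mk_pair(0, 1), boot = 100, seed = 3)
  expect_lt(abs(t_null$theta_I), 2.5 * t_null$se + 0.15)
  expect_equal(t_null$z, t_null$theta_I / t_null$se)

  t_alt <- gu_type1(mk_pair(0.8, 2), boot = 100, seed = 4)
  expect_gt(t_alt$theta_I, t_null$theta_I)
  expect_gte(t_alt$theta_I_ML, 0)
  expect_lte(t_alt$theta_I_ML, 1)
  expect_gte(t_alt$lrt, 0)
})
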