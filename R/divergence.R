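# Gu type-I (rate-shift) and type-II (radical property-shift) functional
# divergence between two duplicate clades of a protein alignment, with
# radical/conserved substitution classification, ancestral-state
# reconstruction and per-site posterior profiles.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# charge classes: negative {D,E}, positive {K,R,H}, neutral otherwise
.aa_charge <- setNames(rep("neutral", 20), .AA20)
.aa_charge[c("D", "E")] <- "negative"
.aa_charge[c("K", "R", "H")] <- "positive"

# hydropathy split by the sign of the Kyte-Doolittle index:
# hydrophobic (positive KD): A C F I L M V; hydrophilic otherwise
.aa_hydro <- setNames(rep("hydrophilic", 20), .AA20)
.aa_hydro[c("A", "C", "F", "I", "L", "M", "V")] <- "hydrophobic"

#' Classify an amino-acid change as conserved or radical
#'
#' A change is radical iff it alters the charge class (positive / negative /
#' neutral) or the hydropathy class (hydrophobic / hydrophilic, split by the
#' sign of the Kyte-Doolittle index); otherwise conserved.  The partition is
#' fixed and documented; nonstandard residues are masked (`NA`).
#' The classification is symmetric in its arguments.
#'
#' @param aa_from,aa_to single-letter amino acids.
#' @return `"conserved"`, `"radical"`, or `NA` for nonstandard input.
#' @export
classify_change <- function(aa_from, aa_to) {
  out <- rep(NA_character_, length(aa_from))
  ok <- aa_from %in% .AA20 & aa_to %in% .AA20
  rad <- .aa_charge[aa_from] != .aa_charge[aa_to] |
    .aa_hydro[aa_from] != .aa_hydro[aa_to]
  out[ok] <- ifelse(rad[ok], "radical", "conserved")
  out
}

# neutral expectation of the radical proportion: fraction of radical changes
# among all single-nucleotide nonsynonymous sense-codon changes (unweighted)
radical_proportion_neutral <- function(code = genetic_code()) {
  key <- paste0(code$id, "_piR")
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  cs <- codon_setup(code)
  nonsyn <- which(cs$type == 3L | cs$type == 4L, arr.ind = TRUE)
  cls <- classify_change(cs$aa[nonsyn[, 1L]], cs$aa[nonsyn[, 2L]])
  piR <- mean(cls == "radical", na.rm = TRUE)
  .codon_env[[key]] <- piR
  piR
}

# 20-state Poisson amino-acid transition matrix: equal rates, equal
# frequencies; t = expected substitutions per site
.aa_P <- function(t) {
  e <- exp(-20 / 19 * t)
  P <- matrix((1 - e) / 20, 20, 20, dimnames = list(.AA20, .AA20))
  diag(P) <- 1 / 20 + 19 / 20 * e
  P
}

#' Marginal ancestral amino-acid reconstruction for a clade
#'
#' Marginal maximum-likelihood reconstruction under a Poisson (equal-rates)
#' amino-acid replacement model via a two-pass (up/down messages) pruning
#' algorithm; per-site within-clade substitution counts are obtained from
#' state changes along branches of the reconstructed tree.  Ties and missing
#' tips default to the most probable state.  All-gap sites are masked.
#'
#' @param x a protein [aln()] restricted to the clade.
#' @param tree rooted clade tree (tips in `x`); built by midpoint-rooted NJ
#'   on p-distances when `NULL`.  Branches without lengths get the mean
#'   pairwise p-distance / 2.
#' @param method `"ml"` (marginal ML) or `"parsimony"` (Fitch counts only).
#' @return list with `ancestral` (root state per site), `changes` (per-site
#'   substitution count), `tree`, `node_states` (site x node MAP states).
#' @export
ancestral_states <- function(x, tree = NULL, method = c("ml", "parsimony")) {
  method <- match.arg(method)
  m <- unclass(x)
  n <- nrow(m); L <- ncol(m)
  if (is.null(tree)) {
    D <- .aa_pdist(m)
    tree <- neighbor_joining(D)
  }
  if (is.null(tree$edge.length) || all(tree$edge.length == 0)) {
    d0 <- mean(.aa_pdist(m)[upper.tri(diag(n))])
    tree$edge.length <- rep(max(d0 / 2, 0.05), nrow(tree$edge))
  }
  if (!ape::is.rooted(tree)) {
    # midpoint rooting; nearly-identical sequences can defeat it, in which
    # case any rooting serves (the Poisson model is reversible)
    tree <- tryCatch(phangorn::midpoint(tree), error = function(e)
      ape::root(tree, tree$tip.label[1L], resolve.root = TRUE))
    if (!ape::is.rooted(tree) || anyNA(tree$edge))
      tree <- ape::root(ape::unroot(tree), tree$tip.label[1L],
                        resolve.root = TRUE)
  }
  tree$edge.length <- pmax(tree$edge.length, 1e-4)
  tre <- reorder(tree, "postorder")
  edges <- tre$edge; el <- tre$edge.length
  ntip <- length(tre$tip.label)
  tipidx <- match(tre$tip.label, rownames(m))
  if (anyNA(tipidx)) stop("input-error: tree tips missing from alignment")
  nnode <- ntip + tre$Nnode
  root <- edges[nrow(edges), 1L]
  Ps <- lapply(el, .aa_P)
  # tip likelihoods
  tipmat <- function(i) {
    v <- m[tipidx[i], ]
    M <- matrix(1, 20, L, dimnames = list(.AA20, NULL))
    ok <- v %in% .AA20
    M[, ok] <- 0
    M[cbind(match(v[ok], .AA20), which(ok))] <- 1
    M
  }
  # up (post-order) partials
  down <- vector("list", nnode)   # conditional likelihood of subtree below
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    base <- if (child <= ntip) tipmat(child) else {
      d <- down[[child]]
      d / rep(pmax(apply(d, 2L, max), 1e-300), each = 20)
    }
    contrib <- Ps[[e]] %*% base
    down[[par]] <- if (is.null(down[[par]])) contrib else down[[par]] * contrib
  }
  # down (pre-order) messages: up[[node]] = likelihood of everything outside
  up <- vector("list", nnode)
  up[[root]] <- matrix(1 / 20, 20, L)
  for (e in rev(seq_len(nrow(edges)))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    if (child <= ntip) next
    sibs <- setdiff(which(edges[, 1L] == par), e)
    msg <- up[[par]]
    for (se in sibs) {
      sc <- edges[se, 2L]
      base <- if (sc <= ntip) tipmat(sc) else {
        d <- down[[sc]]
        d / rep(pmax(apply(d, 2L, max), 1e-300), each = 20)
      }
      msg <- msg * (Ps[[se]] %*% base)
    }
    up[[child]] <- crossprod(Ps[[e]], msg)
    up[[child]] <- up[[child]] /
      rep(pmax(apply(up[[child]], 2L, max), 1e-300), each = 20)
  }
  # MAP states per node
  node_states <- matrix(NA_character_, L, nnode)
  for (nd in seq_len(nnode)) {
    if (nd <= ntip) {
      v <- m[tipidx[nd], ]
      node_states[, nd] <- ifelse(v %in% .AA20, v, NA)
    } else {
      post <- down[[nd]] * up[[nd]]
      node_states[, nd] <- .AA20[max.col(t(post), ties.method = "first")]
    }
  }
  allgap <- colSums(matrix(m %in% .AA20, n)) == 0
  node_states[allgap, ] <- NA
  # per-site substitution counts along branches
  changes <- integer(L)
  if (method == "parsimony") {
    changes <- .fitch_counts(m, tre, tipidx)
  } else {
    for (e in seq_len(nrow(edges))) {
      a <- node_states[, edges[e, 1L]]; b <- node_states[, edges[e, 2L]]
      ok <- !is.na(a) & !is.na(b)
      changes[ok] <- changes[ok] + (a[ok] != b[ok])
    }
  }
  anc <- node_states[, root]
  list(ancestral = anc, changes = changes, tree = tre,
       node_states = node_states)
}

.aa_pdist <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  good <- matrix(m %in% .AA20, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- good[i, ] & good[j, ]
    D[i, j] <- D[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
  }
  D
}

.fitch_counts <- function(m, tre, tipidx) {
  edges <- tre$edge; ntip <- length(tre$tip.label)
  L <- ncol(m)
  counts <- integer(L)
  sets <- vector("list", ntip + tre$Nnode)
  for (s in seq_len(L)) {
    for (i in seq_len(ntip)) {
      v <- m[tipidx[i], s]
      sets[[i]] <- if (v %in% .AA20) v else .AA20
    }
    cnt <- 0L
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; child <- edges[e, 2L]
      cs <- sets[[child]]
      if (is.null(sets[[par]])) { sets[[par]] <- cs; next }
      inter <- intersect(sets[[par]], cs)
      if (length(inter)) sets[[par]] <- inter else {
        sets[[par]] <- union(sets[[par]], cs); cnt <- cnt + 1L
      }
    }
    counts[s] <- cnt
    sets[(ntip + 1L):length(sets)] <- list(NULL)
  }
  counts
}

#' Build a cluster pair for divergence analyses
#'
#' @param x protein [aln()] containing both clades.
#' @param tips1,tips2 disjoint tip sets (each >= 3).
#' @param tree1,tree2 optional rooted clade trees.
#' @return a `cluster_pair` list with per-clade sub-alignments and trees.
#' @export
cluster_pair <- function(x, tips1, tips2, tree1 = NULL, tree2 = NULL) {
  stopifnot(length(intersect(tips1, tips2)) == 0L,
            length(tips1) >= 3L, length(tips2) >= 3L,
            all(c(tips1, tips2) %in% rownames(x)))
  m <- unclass(x)
  a1 <- aln(m[tips1, , drop = FALSE], type = "protein")
  a2 <- aln(m[tips2, , drop = FALSE], type = "protein")
  structure(list(aln1 = a1, aln2 = a2, tips1 = tips1, tips2 = tips2,
                 tree1 = tree1, tree2 = tree2, L = ncol(m)),
            class = "cluster_pair")
}

#' Gu (1999) type-I functional divergence
#'
#' Model-free estimator: the coefficient of rate correlation between the two
#' clades' per-site substitution counts, corrected for Poisson sampling
#' noise, gives `theta_I = 1 - r_lambda` with
#' `r_lambda = cov(X,Y) / sqrt((var(X)-mean(X))(var(Y)-mean(Y)))`.
#' The ML estimator fits a two-state site mixture (F0: shared gamma rate
#' across clades; F1: independent rates) by maximum likelihood with
#' negative-binomial marginals, and an LRT against `theta_I = 0`.
#' Standard errors are site-bootstrap based (`boot` replicates).
#'
#' @param pair a [cluster_pair()].
#' @param boot bootstrap replicates for the SEs (paper-style default 500).
#' @param seed RNG seed for the bootstrap.
#' @return `type1_result`: list with `theta_I`, `se`, `z`, `p`,
#'   `theta_I_ML`, `se_ML`, `alpha`, `lrt`, `p_lrt`, `counts` (site x 2).
#' @export
gu_type1 <- function(pair, boot = 500L, seed = NULL) {
  stopifnot(inherits(pair, "cluster_pair"))
  if (!is.null(seed)) set.seed(seed)
  r1 <- ancestral_states(pair$aln1, pair$tree1)
  r2 <- ancestral_states(pair$aln2, pair$tree2)
  X <- r1$changes; Y <- r2$changes
  est <- function(X, Y) {
    vx <- var(X) - mean(X); vy <- var(Y) - mean(Y)
    if (is.na(vx) || is.na(vy) || vx <= 0 || vy <= 0) return(NA_real_)
    1 - cov(X, Y) / sqrt(vx * vy)
  }
  th <- est(X, Y)
  if (is.na(th))
    stop("undefined-result: no rate variance beyond Poisson noise in a clade")
  bs <- vapply(seq_len(boot), function(b) {
    idx <- sample.int(length(X), replace = TRUE)
    est(X[idx], Y[idx])
  }, 0)
  se <- sd(bs, na.rm = TRUE)
  z <- th / se
  # ML: mixture of shared-rate (negative multinomial) and independent-rate
  # (product negative binomial) site classes, gamma(alpha, alpha) rates
  nb_ll <- function(k, d, alpha)
    lgamma(k + alpha) - lgamma(alpha) - lgamma(k + 1) +
      alpha * log(alpha / (alpha + d)) + k * log(d / (alpha + d))
  shared_ll <- function(X, Y, d1, d2, alpha) {
    tot <- alpha + d1 + d2
    lgamma(X + Y + alpha) - lgamma(alpha) - lgamma(X + 1) - lgamma(Y + 1) +
      alpha * log(alpha / tot) + X * log(d1 / tot) + Y * log(d2 / tot)
  }
  negll <- function(p) {
    th <- plogis(p[1]); alpha <- exp(p[2]); d1 <- exp(p[3]); d2 <- exp(p[4])
    l0 <- shared_ll(X, Y, d1, d2, alpha)
    l1 <- nb_ll(X, d1, alpha) + nb_ll(Y, d2, alpha)
    m <- pmax(l0, l1)
    -sum(m + log((1 - th) * exp(l0 - m) + th * exp(l1 - m)))
  }
  negll0 <- function(p) {   # theta = 0
    alpha <- exp(p[1]); d1 <- exp(p[2]); d2 <- exp(p[3])
    -sum(shared_ll(X, Y, d1, d2, alpha))
  }
  ini <- c(qlogis(max(min(th, 0.9), 0.05)), log(1),
           log(max(mean(X), 0.05)), log(max(mean(Y), 0.05)))
  o1 <- optim(ini, negll, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10))
  o0 <- optim(ini[-1], negll0, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10))
  th_ml <- plogis(o1$par[1])
  lrt_stat <- max(0, 2 * (o0$value - o1$value))
  bs_ml <- vapply(seq_len(min(boot, 100L)), function(b) {
    idx <- sample.int(length(X), replace = TRUE)
    Xb <- X[idx]; Yb <- Y[idx]
    nll <- function(p) {
      thb <- plogis(p[1]); alpha <- exp(p[2]); d1 <- exp(p[3]); d2 <- exp(p[4])
      l0 <- shared_ll(Xb, Yb, d1, d2, alpha)
      l1 <- nb_ll(Xb, d1, alpha) + nb_ll(Yb, d2, alpha)
      m <- pmax(l0, l1)
      -sum(m + log((1 - thb) * exp(l0 - m) + thb * exp(l1 - m)))
    }
    ob <- tryCatch(optim(o1$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 500)),
                   error = function(e) NULL)
    if (is.null(ob)) NA_real_ else plogis(ob$par[1])
  }, 0)
  structure(list(theta_I = th, se = se, z = z,
                 p = pnorm(z, lower.tail = FALSE),
                 theta_I_ML = th_ml, se_ML = sd(bs_ml, na.rm = TRUE),
                 alpha = exp(o1$par[2]), lrt = lrt_stat,
                 p_lrt = pchisq(lrt_stat, 1L, lower.tail = FALSE),
                 counts = cbind(X = X, Y = Y),
                 flagged_out_of_range = th < 0 || th > 1),
            class = "type1_result")
}

#' Gu (2006)-style type-II functional divergence
#'
#' Reconstructs each clade's ancestral sequence, classifies every site as
#' N (no between-ancestor change), C (conserved change) or R (radical
#' change), and estimates the type-II coefficient on the F00 site class
#' (sites without any within-clade change): with observed F00 proportions
#' `P_C` and `P_R` and the neutral radical proportion `pi_R`,
#' \deqn{\hat\theta_{II} = P_R - \frac{\pi_R}{1-\pi_R} P_C}
#' (conserved changes are attributed to nonfunctional divergence at neutral
#' radical odds; type-II sites are modeled as radical).  The SE is a
#' site-bootstrap SE (`boot` replicates) and `z = theta_II / SE`.  Estimates
#' outside [0, 1] are flagged, not clamped.
#'
#' @param pair a [cluster_pair()].
#' @param boot bootstrap replicates (paper-style default 1000).
#' @param seed RNG seed.
#' @param code genetic code for the neutral radical proportion.
#' @return `type2_result`: list with `theta_II`, `se`, `z`, `p`, `N`, `C`,
#'   `R` (site counts over all sites), `F00` proportions (`F00_N`, `F00_C`,
#'   `F00_R`), `ar_over_pir`, `gr_over_gc`, `pi_R`, per-site `site_class`
#'   and `site_f00`, plus the clade ancestors.
#' @export
gu_type2 <- function(pair, boot = 1000L, seed = NULL, code = genetic_code()) {
  stopifnot(inherits(pair, "cluster_pair"))
  if (!is.null(seed)) set.seed(seed)
  r1 <- ancestral_states(pair$aln1, pair$tree1)
  r2 <- ancestral_states(pair$aln2, pair$tree2)
  a1 <- r1$ancestral; a2 <- r2$ancestral
  ok <- !is.na(a1) & !is.na(a2)
  cls <- rep(NA_character_, pair$L)
  cls[ok & a1 == a2] <- "N"
  chg <- ok & a1 != a2
  cls[chg] <- ifelse(classify_change(a1[chg], a2[chg]) == "radical", "R", "C")
  f00 <- ok & r1$changes == 0L & r2$changes == 0L
  piR <- radical_proportion_neutral(code)
  est <- function(cls, f00) {
    m <- sum(f00 & !is.na(cls))
    if (m == 0L) return(NA_real_)
    pC <- sum(cls[f00] == "C", na.rm = TRUE) / m
    pR <- sum(cls[f00] == "R", na.rm = TRUE) / m
    pR - piR / (1 - piR) * pC
  }
  th <- est(cls, f00)
  Ntot <- sum(cls == "N", na.rm = TRUE)
  Ctot <- sum(cls == "C", na.rm = TRUE)
  Rtot <- sum(cls == "R", na.rm = TRUE)
  if (Ctot + Rtot == 0L) {
    res <- list(theta_II = 0, se = 0, z = NA_real_, p = NA_real_,
                N = Ntot, C = 0L, R = 0L,
                F00_N = mean(f00 & cls == "N", na.rm = TRUE), F00_C = 0,
                F00_R = 0, ar_over_pir = NA_real_, gr_over_gc = NA_real_,
                pi_R = piR, site_class = cls, site_f00 = f00,
                anc1 = a1, anc2 = a2, flagged_out_of_range = FALSE)
    class(res) <- "type2_result"
    return(res)
  }
  bs <- vapply(seq_len(boot), function(b) {
    idx <- sample.int(pair$L, replace = TRUE)
    est(cls[idx], f00[idx])
  }, 0)
  se <- sd(bs, na.rm = TRUE)
  z <- if (se > 0) th / se else NA_real_
  nsites <- sum(!is.na(cls))
  aR <- Rtot / (Rtot + Ctot)           # radical fraction among changes
  res <- list(theta_II = th, se = se, z = z,
              p = if (is.na(z)) NA_real_ else pnorm(z, lower.tail = FALSE),
              N = Ntot, C = Ctot, R = Rtot,
              F00_N = sum(f00 & cls == "N", na.rm = TRUE) / nsites,
              F00_C = sum(f00 & cls == "C", na.rm = TRUE) / nsites,
              F00_R = sum(f00 & cls == "R", na.rm = TRUE) / nsites,
              ar_over_pir = aR / piR, gr_over_gc = Rtot / max(Ctot, 1L),
              pi_R = piR, site_class = cls, site_f00 = f00,
              anc1 = a1, anc2 = a2,
              flagged_out_of_range = !is.na(th) && (th < 0 || th > 1))
  class(res) <- "type2_result"
  res
}

#' @export
print.type2_result <- function(x, ...) {
  cat(sprintf(
    "type-II divergence: theta_II = %.4f +/- %.4f (z = %.3f, p = %.3g)%s\n",
    x$theta_II, x$se, x$z, x$p,
    if (isTRUE(x$flagged_out_of_range)) " [out of range]" else ""))
  cat(sprintf("  N/C/R = %d/%d/%d; F00 N/C/R = %.3f/%.3f/%.3f; aR/piR = %.3f\n",
              x$N, x$C, x$R, x$F00_N, x$F00_C, x$F00_R, x$ar_over_pir))
  invisible(x)
}

#' Per-site posterior ratio profile for type-II divergence
#'
#' Posterior odds that a site belongs to the type-II divergent class, from
#' the fitted mixture: divergent sites always differ between the clade
#' ancestors and are radical with probability `a_R`; nonfunctional sites
#' change with the estimated background change probability and are radical
#' with neutral probability `pi_R`.  The identity ratio = p/(1-p), i.e.
#' probability = ratio/(1+ratio), holds exactly; a ratio > 4 corresponds to
#' posterior probability > 0.8.
#'
#' @param t2 a [gu_type2()] result.
#' @param threshold report sites with ratio above this value (default 4).
#' @return data.frame with `site`, `class`, `ratio`, `posterior`, `flagged`.
#' @export
site_posterior_profile <- function(t2, threshold = 4) {
  stopifnot(inherits(t2, "type2_result"))
  cls <- t2$site_class; f00 <- t2$site_f00
  th <- min(max(t2$theta_II, 1e-6), 1 - 1e-6)
  m <- sum(f00 & !is.na(cls))
  pC <- if (m > 0) sum(cls[f00] == "C", na.rm = TRUE) / m else 0
  # background change probability among non-divergent F00 sites
  pch <- min(max(pC / max(1 - t2$pi_R, 1e-6), 1e-6), 1 - 1e-6)
  aR <- if (!is.na(t2$ar_over_pir)) min(max(t2$pi_R * t2$ar_over_pir, t2$pi_R),
                                        1 - 1e-6) else 0.5
  lik_div <- ifelse(is.na(cls), NA,
    ifelse(cls == "R", aR, ifelse(cls == "C", 1 - aR, 1e-6)))
  lik_bg <- ifelse(is.na(cls), NA,
    ifelse(cls == "N", 1 - pch,
           ifelse(cls == "R", pch * t2$pi_R, pch * (1 - t2$pi_R))))
  ratio <- th * lik_div / ((1 - th) * pmax(lik_bg, 1e-300))
  post <- ratio / (1 + ratio)
  data.frame(site = seq_along(cls), class = cls, ratio = ratio,
             posterior = post, flagged = !is.na(ratio) & ratio > threshold)
}
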