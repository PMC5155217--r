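# 61-state codon substitution machinery: Goldman-Yang-style rate matrix
# (single-nucleotide steps; kappa for transitions, omega for nonsynonymous
# changes, target-codon frequencies), reversible eigendecomposition, and a
# scaled Felsenstein pruning likelihood over site patterns with site-class
# mixtures and per-branch (foreground/background) omega regimes.

.codon_env <- new.env(parent = emptyenv())

# precomputed single-step structure of the sense-codon space
codon_setup <- function(code = genetic_code()) {
  key <- code$id
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  sense <- code$sense
  K <- length(sense)
  nt <- c("A", "C", "G", "T")
  ts_pair <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  cm <- do.call(rbind, strsplit(sense, ""))
  type <- matrix(0L, K, K)  # 0 none; 1 syn tv; 2 syn ts; 3 nonsyn tv; 4 nonsyn ts
  aa <- code$aa[sense]
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    diff <- which(cm[i, ] != cm[j, ])
    if (length(diff) != 1L) next
    ts <- ts_pair(cm[i, diff], cm[j, diff])
    syn <- aa[i] == aa[j]
    type[i, j] <- if (syn && !ts) 1L else if (syn && ts) 2L else
      if (!syn && !ts) 3L else 4L
  }
  res <- list(sense = sense, K = K, type = type, aa = aa,
              pos = cm, code = code)
  .codon_env[[key]] <- res
  res
}

# equilibrium codon frequencies
codon_freqs <- function(ca, method = c("F3x4", "equal", "empirical"),
                        code = genetic_code()) {
  method <- match.arg(method)
  cs <- codon_setup(code)
  if (method == "equal") {
    f <- rep(1 / cs$K, cs$K)
  } else {
    cods <- codon_strings(ca)
    cods <- cods[!is.na(cods)]
    if (method == "empirical") {
      tab <- table(factor(cods, levels = cs$sense))
      f <- (as.numeric(tab) + 0.1) / sum(as.numeric(tab) + 0.1)
    } else {                                  # F3x4
      m <- do.call(rbind, strsplit(cods, ""))
      posfreq <- lapply(1:3, function(p) {
        t <- table(factor(m[, p], levels = c("A", "C", "G", "T")))
        (as.numeric(t) + 0.5) / sum(as.numeric(t) + 0.5)
      })
      nt <- c("A", "C", "G", "T")
      f <- apply(cs$pos, 1L, function(cd)
        posfreq[[1]][match(cd[1], nt)] * posfreq[[2]][match(cd[2], nt)] *
        posfreq[[3]][match(cd[3], nt)])
      f <- f / sum(f)
    }
  }
  f <- pmax(f, 1e-10)
  f / sum(f)
}

# rate matrix eigendecomposition for given kappa/omega/pi; returns structure
# with everything needed to form P(t) = D^{-1/2} U exp(L t) U' D^{1/2}
codon_eigen <- function(kappa, omega, pi, cs) {
  # memoized on (kappa, omega, pi): the branch-length phase of model fitting
  # re-evaluates the same generator thousands of times
  memo_key <- paste(format(c(kappa, omega, pi[1], pi[17], pi[61], sum(pi^2)),
                           digits = 15), collapse = "|")
  if (is.null(.codon_env$eigcache))
    .codon_env$eigcache <- new.env(parent = emptyenv())
  hit <- .codon_env$eigcache[[memo_key]]
  if (!is.null(hit)) return(hit)
  K <- cs$K
  rate <- matrix(0, K, K)
  ty <- cs$type
  rate[ty == 1L] <- 1
  rate[ty == 2L] <- kappa
  rate[ty == 3L] <- omega
  rate[ty == 4L] <- kappa * omega
  Q <- rate * rep(pi, each = K)     # Q[i,j] = rate_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("simulation-error: all-zero rate matrix")
  Q <- Q / scale        # normalized to one expected substitution per unit t;
                        # `rate_raw` keeps the pre-normalization rate so that
                        # mixtures can share a common time scale
  d <- sqrt(pi)
  B <- Q * outer(d, 1 / d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  res <- list(values = e$values,
              A = e$vectors / d,     # A[i,k] = U[i,k]/d[i]  (= D^{-1/2} U)
              Bt = t(e$vectors * d), # Bt[k,j] = U[j,k]*d[j]
              Q = Q, pi = pi, rate_raw = scale)
  if (length(ls(.codon_env$eigcache)) > 4096L)
    .codon_env$eigcache <- new.env(parent = emptyenv())
  .codon_env$eigcache[[memo_key]] <- res
  res
}

# transition probability matrix from a codon_eigen
codon_P <- function(eg, t) {
  P <- eg$A %*% (exp(eg$values * t) * eg$Bt)
  P[P < 0] <- 0
  P
}

# integer codon states (indices into sense codons; NA = masked) and pattern
# compression for a codon alignment
codon_states <- function(ca, code = genetic_code()) {
  cs <- codon_setup(code)
  cods <- codon_strings(ca)
  st <- matrix(match(cods, cs$sense), nrow = nrow(cods),
               dimnames = list(rownames(ca$aln), NULL))
  st
}

codon_patterns <- function(st) {
  key <- apply(st, 2L, paste, collapse = ",")
  u <- unique(key)
  idx <- match(key, u)
  first <- match(u, key)
  list(states = st[, first, drop = FALSE],
       weights = as.numeric(table(factor(idx, levels = seq_along(u)))),
       map = idx)
}

# site-class mixture description: list of classes, each
# list(prop =, w_bg =, w_fg =); fg_edges indexes rows of tree$edge
# (empty integer(0) when no foreground).

# core pruning: per-class per-pattern site likelihoods.
# Returns list(site_lik = npat x nclass matrix of likelihoods (scaled back),
#              log_scale = npat vector shared log-scaling -- folded in).
codon_site_lik <- function(pat, tree, kappa, pi, classes, fg_edges,
                           cs, edge_lengths = NULL) {
  tre <- reorder(tree, "postorder")
  edges <- tre$edge
  if (is.null(edge_lengths)) {
    el <- tre$edge.length
  } else {    # supplied lengths follow the original edge order
    ord <- match(paste(edges[, 1L], edges[, 2L]),
                 paste(tree$edge[, 1L], tree$edge[, 2L]))
    el <- edge_lengths[ord]
  }
  if (is.null(el)) stop("input-error: tree has no branch lengths")
  ntip <- length(tre$tip.label)
  nnode <- tre$Nnode
  tipidx <- match(tre$tip.label, rownames(pat$states))
  if (anyNA(tipidx))
    stop("input-error: tree tips missing from alignment: ",
         paste(tre$tip.label[is.na(tipidx)], collapse = ", "))
  npat <- ncol(pat$states)
  K <- cs$K
  # distinct omegas across classes/branch roles -> eigen cache
  omegas <- unique(unlist(lapply(classes, function(cl) c(cl$w_bg, cl$w_fg))))
  egs <- lapply(omegas, function(w) codon_eigen(kappa, w, pi, cs))
  names(egs) <- as.character(omegas)
  # fg_edges index rows of the ORIGINAL tree$edge; remap to postorder
  ord_orig <- match(paste(edges[, 1L], edges[, 2L]),
                    paste(tree$edge[, 1L], tree$edge[, 2L]))
  is_fg <- ord_orig %in% fg_edges
  nclass <- length(classes)
  # common time scale: branch lengths are expected substitutions per codon
  # averaged over site classes, so classes with larger omega run faster
  props <- vapply(classes, `[[`, 0, "prop")
  props <- props / sum(props)
  rate_of <- function(w) egs[[as.character(w)]]$rate_raw
  wmat_bg <- vapply(classes, `[[`, 0, "w_bg")
  wmat_fg <- vapply(classes, `[[`, 0, "w_fg")
  mean_rate_bg <- sum(props * vapply(wmat_bg, rate_of, 0))
  mean_rate_fg <- sum(props * vapply(wmat_fg, rate_of, 0))
  out <- matrix(0, npat, nclass)
  Pcache <- new.env(parent = emptyenv())   # classes often share (w, t) pairs
  for (ci in seq_len(nclass)) {
    cl <- classes[[ci]]
    # P per edge
    Plist <- vector("list", nrow(edges))
    for (e in seq_len(nrow(edges))) {
      w <- if (is_fg[e]) cl$w_fg else cl$w_bg
      rel <- rate_of(w) / if (is_fg[e]) mean_rate_fg else mean_rate_bg
      key <- paste(w, e)
      P <- Pcache[[key]]
      if (is.null(P)) {
        P <- codon_P(egs[[as.character(w)]], el[e] * rel)
        Pcache[[key]] <- P
      }
      Plist[[e]] <- P
    }
    partial <- vector("list", ntip + nnode)
    logscale <- numeric(npat)
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; child <- edges[e, 2L]
      if (child <= ntip) {
        stv <- pat$states[tipidx[child], ]
        contrib <- matrix(1, K, npat)
        ok <- !is.na(stv)
        if (any(ok)) contrib[, ok] <- Plist[[e]][, stv[ok], drop = FALSE]
      } else {
        cp <- partial[[child]]
        sc <- colSums(cp)           # any positive per-column factor works
        sc[sc <= 0] <- 1
        logscale <- logscale + log(sc)
        contrib <- Plist[[e]] %*% (cp / rep(sc, each = K))
      }
      partial[[par]] <- if (is.null(partial[[par]])) contrib else
        partial[[par]] * contrib
    }
    root <- edges[nrow(edges), 1L]
    lik <- colSums(pi * partial[[root]])
    out[, ci] <- log(pmax(lik, 1e-300)) + logscale
  }
  out   # npat x nclass matrix of per-class log site likelihoods
}

# total log-likelihood of a mixture given per-class log site likelihoods
mix_lnL <- function(loglik_mat, props, weights) {
  m <- apply(loglik_mat, 1L, max)
  lik <- exp(loglik_mat - m) %*% props
  sum(weights * (log(pmax(lik, 1e-300)) + m))
}

#' Per-site log-likelihoods under a codon model
#'
#' Felsenstein pruning over the sense-codon space with the mixture defined by
#' `classes`.  Rates are zero for multi-nucleotide changes; single-nucleotide
#' changes are proportional to the target codon frequency, multiplied by
#' `kappa` for transitions and by the class omega for nonsynonymous changes;
#' the generator is scaled to one expected substitution per unit branch
#' length at equilibrium.
#'
#' @param ca a codon alignment ([to_codon_alignment()]).
#' @param tree `phylo` tree with branch lengths; tips must be alignment ids.
#' @param kappa transition/transversion rate ratio.
#' @param classes list of site classes, each `list(prop=, w_bg=, w_fg=)`;
#'   defaults to a single-ratio class.
#' @param omega shortcut when a single-ratio model is wanted.
#' @param fg_edges integer indices into `tree$edge` rows treated as
#'   foreground (w_fg applies there).
#' @param freqs `"F3x4"`, `"equal"`, `"empirical"`, or a numeric vector of 61
#'   codon frequencies.
#' @param code a [genetic_code()].
#' @return list with `site_lnL` (per codon site), `lnL` (their sum),
#'   `class_loglik` (pattern x class matrix), `pattern_map`, `weights`.
#' @export
site_log_likelihoods <- function(ca, tree, kappa = 2, omega = 1,
                                 classes = NULL, fg_edges = integer(0),
                                 freqs = "F3x4", code = genetic_code()) {
  cs <- codon_setup(code)
  if (is.null(classes)) classes <- list(list(prop = 1, w_bg = omega, w_fg = omega))
  pi <- if (is.numeric(freqs)) freqs else codon_freqs(ca, freqs, code)
  st <- codon_states(ca, code)
  keep <- !ca$pseudogene[rownames(st)]
  st <- st[keep, , drop = FALSE]
  pat <- codon_patterns(st)
  ll <- codon_site_lik(pat, tree, kappa, pi, classes, fg_edges, cs)
  props <- vapply(classes, `[[`, 0, "prop")
  props <- props / sum(props)
  m <- apply(ll, 1L, max)
  site_pat <- log(pmax(exp(ll - m) %*% props, 1e-300)) + m
  list(site_lnL = as.numeric(site_pat)[pat$map],
       lnL = sum(pat$weights * site_pat),
       class_loglik = ll, pattern_map = pat$map, weights = pat$weights,
       props = props, pi = pi)
}
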