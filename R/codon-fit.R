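# Site-class codon model templates, maximum-likelihood fitting, LRTs and
# naive empirical Bayes site posteriors.
#
# Templates: M0 (one ratio), free (per-branch ratio), M1a (nearly neutral),
# M2a (positive selection), M7 (beta), M8 (beta & omega_s), M8a (beta &
# omega_s = 1), bsA (branch-site model A), bsA-null (foreground omega2 = 1).
#
# Site-class models hold branch lengths fixed by default (estimated under M0
# on the same tree beforehand) so that the nesting chains
# lnL(M2a) >= lnL(M1a), lnL(M8) >= lnL(M8a) >= lnL(M7), lnL(bsA) >=
# lnL(bsA-null) are exact; set optimise_branch_lengths = TRUE to re-optimize.

.BETA_K <- 8L   # number of beta discretization categories for M7/M8/M8a

.beta_classes <- function(p, q, K = .BETA_K) {
  # equal-probability categories, represented by quantile midpoints;
  # shape parameters clamped to a numerically safe range
  p <- min(max(p, 0.005), 99); q <- min(max(q, 0.005), 99)
  qs <- suppressWarnings(qbeta((seq_len(K) - 0.5) / K, p, q))
  qs[!is.finite(qs)] <- 0.5
  qs <- pmin(pmax(qs, 1e-6), 1 - 1e-6)
  lapply(qs, function(w) list(prop = 1 / K, w_bg = w, w_fg = w))
}

# template definitions: par vector <-> classes + np bookkeeping.
# Parameters are unconstrained reals; transforms documented per template.
.template <- function(name) {
  switch(name,
    M0 = list(
      npar = 1L,
      init = function() log(0.3),
      classes = function(par, fg) list(list(prop = 1, w_bg = exp(par),
                                            w_fg = exp(par))),
      report = function(par) list(omega = exp(par))),
    M1a = list(
      npar = 2L,
      init = function() c(qlogis(0.7), qlogis(0.2)),
      classes = function(par, fg) {
        p0 <- plogis(par[1]); w0 <- plogis(par[2])
        list(list(prop = p0, w_bg = w0, w_fg = w0),
             list(prop = 1 - p0, w_bg = 1, w_fg = 1))
      },
      report = function(par) list(p0 = plogis(par[1]), omega0 = plogis(par[2]),
                                  p1 = 1 - plogis(par[1]))),
    M2a = list(
      npar = 4L,
      init = function() c(1.5, 0, qlogis(0.2), log(1)),
      classes = function(par, fg) {
        pr <- exp(c(par[1], par[2], 0)); pr <- pr / sum(pr)
        w0 <- plogis(par[3]); w2 <- 1 + exp(par[4])
        list(list(prop = pr[1], w_bg = w0, w_fg = w0),
             list(prop = pr[2], w_bg = 1, w_fg = 1),
             list(prop = pr[3], w_bg = w2, w_fg = w2))
      },
      report = function(par) {
        pr <- exp(c(par[1], par[2], 0)); pr <- pr / sum(pr)
        list(p0 = pr[1], p1 = pr[2], p2 = pr[3],
             omega0 = plogis(par[3]), omega2 = 1 + exp(par[4]))
      }),
    M7 = list(
      npar = 2L,
      init = function() c(log(0.5), log(2)),
      classes = function(par, fg) .beta_classes(exp(par[1]), exp(par[2])),
      report = function(par) list(p = exp(par[1]), q = exp(par[2]))),
    M8 = list(
      npar = 4L,
      init = function() c(log(0.5), log(2), qlogis(0.9), log(1)),
      classes = function(par, fg) {
        p0 <- plogis(par[3]); ws <- 1 + exp(par[4])
        cl <- .beta_classes(exp(par[1]), exp(par[2]))
        cl <- lapply(cl, function(c0) { c0$prop <- c0$prop * p0; c0 })
        c(cl, list(list(prop = 1 - p0, w_bg = ws, w_fg = ws)))
      },
      report = function(par) list(p = exp(par[1]), q = exp(par[2]),
                                  p0 = plogis(par[3]),
                                  omega_s = 1 + exp(par[4]))),
    M8a = list(
      npar = 3L,
      init = function() c(log(0.5), log(2), qlogis(0.9)),
      classes = function(par, fg) {
        p0 <- plogis(par[3])
        cl <- .beta_classes(exp(par[1]), exp(par[2]))
        cl <- lapply(cl, function(c0) { c0$prop <- c0$prop * p0; c0 })
        c(cl, list(list(prop = 1 - p0, w_bg = 1, w_fg = 1)))
      },
      report = function(par) list(p = exp(par[1]), q = exp(par[2]),
                                  p0 = plogis(par[3]), omega_s = 1)),
    bsA = list(
      npar = 4L,
      init = function() c(qlogis(0.7), qlogis(0.5), qlogis(0.2), log(1)),
      classes = function(par, fg) .bsA_classes(par, fixed_w2 = NULL),
      report = function(par) .bsA_report(par, fixed_w2 = NULL)),
    `bsA-null` = list(
      npar = 3L,
      init = function() c(qlogis(0.7), qlogis(0.5), qlogis(0.2)),
      classes = function(par, fg) .bsA_classes(par, fixed_w2 = 1),
      report = function(par) .bsA_report(par, fixed_w2 = 1)),
    stop("unknown model template: ", name))
}

# branch-site model A classes: proportions p0, p1 and p2a/p2b in ratio
# p0:p1 of the remainder; background {w0, 1, w0, 1}, foreground {w0, 1, w2, w2}
.bsA_classes <- function(par, fixed_w2 = NULL) {
  s <- plogis(par[1])              # p0 + p1
  f <- plogis(par[2])              # p0 / (p0 + p1)
  p0 <- s * f; p1 <- s * (1 - f)
  p2a <- (1 - s) * f; p2b <- (1 - s) * (1 - f)
  w0 <- plogis(par[3])
  w2 <- if (is.null(fixed_w2)) 1 + exp(par[4]) else fixed_w2
  list(list(prop = p0, w_bg = w0, w_fg = w0),
       list(prop = p1, w_bg = 1, w_fg = 1),
       list(prop = p2a, w_bg = w0, w_fg = w2),
       list(prop = p2b, w_bg = 1, w_fg = w2))
}

.bsA_report <- function(par, fixed_w2 = NULL) {
  cl <- .bsA_classes(par, fixed_w2)
  list(p0 = cl[[1]]$prop, p1 = cl[[2]]$prop, p2a = cl[[3]]$prop,
       p2b = cl[[4]]$prop, omega0 = cl[[1]]$w_bg,
       omega2 = cl[[3]]$w_fg)
}

#' Embed a fitted null model's solution as a starting point for a nesting
#' alternative
#'
#' Supported nestings: M1a -> M2a, M7 -> M8 / M8a, M8a -> M8,
#' bsA-null -> bsA.  Starting the alternative's optimizer at the embedded
#' null solution guarantees `lnL(alt) >= lnL(null)` numerically.
#'
#' @param fit a [fit_model()] result (the null).
#' @param to_template the alternative template name.
#' @return list with `par` (parameter vector in the alternative's
#'   parameterization) and `kappa` (the null's fitted kappa); accepted by
#'   `fit_model(init_par=)`.
#' @export
embed_init <- function(fit, to_template) {
  eps <- log(1e-6)            # omega_extra = 1 + 1e-6; proportions ~ 1e-4
  from <- fit$template; par <- fit$par
  p <- if (from == "M1a" && to_template == "M2a") {
    p0 <- plogis(par[1]); p1 <- 1 - p0; p2 <- 1e-4
    c(log(p0 / p2), log(p1 / p2), par[2], eps)
  } else if (from == "M7" && to_template %in% c("M8", "M8a")) {
    base <- c(par[1], par[2], qlogis(1 - 1e-4))
    if (to_template == "M8") c(base, eps) else base
  } else if (from == "M8a" && to_template == "M8") {
    c(par, eps)
  } else if (from == "bsA-null" && to_template == "bsA") {
    c(par, eps)
  } else stop("unsupported nesting: ", from, " -> ", to_template)
  list(par = p, kappa = fit$kappa)
}

#' Resolve foreground branches from a clade specification
#'
#' @param tree a `phylo` tree.
#' @param tips tip labels of the foreground clade.
#' @param mode `"stem"`: only the branch subtending the clade MRCA (a
#'   whole-clade foreground); `"all"`: every branch inside the clade plus the
#'   stem (all lineages of the clade).
#' @return integer indices into `tree$edge` rows.
#' @export
foreground_edges <- function(tree, tips, mode = c("stem", "all")) {
  mode <- match.arg(mode)
  stopifnot(all(tips %in% tree$tip.label))
  if (length(tips) == 1L) {
    node <- match(tips, tree$tip.label)
    return(which(tree$edge[, 2L] == node))
  }
  mrca <- ape::getMRCA(tree, tips)
  stem <- which(tree$edge[, 2L] == mrca)
  if (mode == "stem") return(stem)
  desc <- .descendant_nodes(tree, mrca)
  c(stem, which(tree$edge[, 1L] %in% c(mrca, desc)))
}

.descendant_nodes <- function(tree, node) {
  out <- integer(0); stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  unique(out)
}

# internal: build objective over (kappa, template params) with fixed branch
# lengths; returns closure list
.make_obj <- function(pat, tree, pi, tmpl, fg_edges, cs) {
  function(kappa, par, el) {
    classes <- tmpl$classes(par, fg_edges)
    props <- vapply(classes, `[[`, 0, "prop")
    ll <- codon_site_lik(pat, tree, kappa, pi, classes, fg_edges, cs,
                         edge_lengths = el)
    mix_lnL(ll, props, attr(pat, "w"))
  }
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Fits one of the model templates (M0, free-ratio, M1a, M2a, M7, M8, M8a,
#' branch-site A and its null) to a codon alignment on a fixed topology.
#' M0 and the free-ratio model optimize branch lengths jointly with the rate
#' parameters (coordinate rounds of bounded quasi-Newton on log branch
#' lengths alternating with the rate parameters).  Site-class models by
#' default keep the branch lengths of the supplied tree fixed (fit M0 first
#' and pass `$tree` on); `optimise_branch_lengths = TRUE` re-optimizes them.
#' Class-model parameters are refit from `restarts` random restarts and the
#' best solution kept.
#'
#' @param ca codon alignment ([to_codon_alignment()]); pseudogene-flagged
#'   sequences are excluded from fitting.
#' @param tree `phylo` with branch lengths (or without, when branch lengths
#'   are optimized; they are then initialized from pairwise p-distances).
#' @param template model name.
#' @param foreground tip labels of the foreground clade (bsA templates).
#' @param foreground_mode `"stem"` (#-style whole-clade branch) or `"all"`
#'   ($-style all clade lineages).
#' @param freqs codon frequency model or numeric vector (see
#'   [site_log_likelihoods()]).
#' @param kappa initial kappa.
#' @param optimise_branch_lengths force joint branch-length optimization.
#' @param restarts random restarts for class-model parameters.
#' @param tol convergence tolerance on lnL.
#' @param init_par optional starting parameter vector (see [embed_init()]);
#'   used for the first restart.
#' @param fix_kappa hold kappa at its supplied value instead of estimating
#'   it (useful for nested-model contrasts where kappa comes from an M0
#'   fit; both members of a contrast must use the same setting).
#' @param code a [genetic_code()].
#' @return object of class `codon_fit`: list with `lnL`, `np`, `mles`
#'   (named list incl. kappa), `per_branch_omega` (free-ratio), `tree` (with
#'   fitted branch lengths), `template`, `fg_edges`, `converged`,
#'   `n_restarts_used`, plus fit internals for downstream posteriors.
#' @export
fit_model <- function(ca, tree, template = "M0", foreground = NULL,
                      foreground_mode = c("stem", "all"), freqs = "F3x4",
                      kappa = 2, optimise_branch_lengths = NULL,
                      restarts = 3L, tol = 1e-6, init_par = NULL,
                      fix_kappa = FALSE, code = genetic_code()) {
  foreground_mode <- match.arg(foreground_mode)
  stopifnot(inherits(ca, "codon_aln"))
  cs <- codon_setup(code)
  pi <- if (is.numeric(freqs)) freqs else codon_freqs(ca, freqs, code)
  st <- codon_states(ca, code)
  st <- st[!ca$pseudogene[rownames(st)], , drop = FALSE]
  tree <- ape::drop.tip(tree, setdiff(tree$tip.label, rownames(st))) %||% tree
  if (!all(tree$tip.label %in% rownames(st)))
    stop("input-error: tree tips missing from alignment")
  pat <- codon_patterns(st[tree$tip.label, , drop = FALSE])
  w <- pat$weights
  attr(pat, "w") <- w
  fg_edges <- if (is.null(foreground)) integer(0) else
    foreground_edges(tree, foreground, foreground_mode)
  if (template %in% c("bsA", "bsA-null") && !length(fg_edges))
    stop("input-error: branch-site model A requires a foreground clade")
  nedge <- nrow(tree$edge)
  # initial branch lengths
  el0 <- tree$edge.length
  if (is.null(el0)) {
    pd <- mean(.pairwise_pdist(st)) %||% 0.2
    el0 <- rep(max(pd, 0.02), nedge)
  }
  el0 <- pmax(el0, 1e-6)
  opt_bl <- if (!is.null(optimise_branch_lengths)) optimise_branch_lengths
    else template %in% c("M0", "free")

  if (template == "free") {
    return(.fit_free_ratio(pat, tree, pi, cs, kappa, el0, tol, w))
  }
  tmpl <- .template(template)
  obj <- .make_obj(pat, tree, pi, tmpl, fg_edges, cs)

  best <- NULL
  n_res <- if (template == "M0") 1L else max(1L, restarts)
  has_pos_class <- template %in% c("M2a", "M8", "bsA")
  if (is.list(init_par)) {             # embed_init() carries the null's kappa
    kappa <- init_par$kappa %||% kappa
    init_par <- init_par$par
  }
  if (!is.null(init_par) && !opt_bl) {
    # exact nested embedding: evaluate once as a floor so that
    # lnL(alternative) can never drop below lnL(null)
    lnL0 <- obj(kappa, init_par, el0)
    best <- list(lnL = lnL0, par = init_par, lk = log(kappa), el = el0,
                 converged = TRUE, restart = 0L)
  }
  for (r in seq_len(n_res)) {
    par <- if (!is.null(init_par) && r == 1L && has_pos_class) {
      p <- init_par; p[length(p)] <- log(1); p   # embedding with omega2 = 2
    } else if (!is.null(init_par) && r == 1L) {
      init_par
    } else {
      p <- tmpl$init()
      if (r > 1L) p <- p + rnorm(length(p), 0, 1)
      p
    }
    lk <- log(kappa)
    el <- el0
    lnL_prev <- -Inf
    conv <- FALSE
    if (!opt_bl) {
      # fixed branch lengths: one simplex pass plus quasi-Newton polish
      fn1 <- if (fix_kappa) function(v) -obj(exp(lk), v, el) else
        function(v) -obj(exp(v[1]), v[-1], el)
      p0 <- if (fix_kappa) par else c(lk, par)
      o1 <- optim(p0, fn1, method = "Nelder-Mead",
                  control = list(maxit = 300, reltol = 1e-8))
      o1 <- tryCatch(
        optim(o1$par, fn1, method = "L-BFGS-B",
              lower = o1$par - 3, upper = o1$par + 3,
              control = list(maxit = 25, factr = 1e6)),
        error = function(e) o1)
      if (fix_kappa) par <- o1$par else {
        lk <- o1$par[1]; par <- o1$par[-1]
      }
      lnL <- -o1$value
      conv <- TRUE
    } else {
      for (round in 1:6) {
        # rate parameters (kappa + template params)
        fn1 <- function(v) -obj(exp(v[1]), v[-1], el)
        o1 <- optim(c(lk, par), fn1, method = "Nelder-Mead",
                    control = list(maxit = 200, reltol = 1e-8))
        lk <- o1$par[1]; par <- o1$par[-1]
        lnL <- -o1$value
        classes <- tmpl$classes(par, fg_edges)
        props <- vapply(classes, `[[`, 0, "prop")
        fn2 <- function(lv) {
          ll <- codon_site_lik(pat, tree, exp(lk), pi, classes, fg_edges, cs,
                               edge_lengths = exp(lv))
          -mix_lnL(ll, props, w)
        }
        o2 <- optim(log(el), fn2, method = "L-BFGS-B",
                    lower = log(1e-7), upper = log(20),
                    control = list(maxit = 50, factr = 1e6))
        el <- exp(o2$par)
        lnL <- -o2$value
        if (abs(lnL - lnL_prev) < max(tol, 1e-4) && round >= 2) {
          conv <- TRUE; break
        }
        lnL_prev <- lnL
      }
    }
    if (is.null(best) || lnL > best$lnL)
      best <- list(lnL = lnL, par = par, lk = lk, el = el, converged = conv,
                   restart = r)
  }
  tree_out <- tree; tree_out$edge.length <- best$el
  mles <- c(list(kappa = exp(best$lk)), tmpl$report(best$par))
  np <- nedge + 1L + tmpl$npar
  structure(list(lnL = best$lnL, np = np, mles = mles,
                 per_branch_omega = NULL, tree = tree_out,
                 template = template, fg_edges = fg_edges,
                 converged = best$converged, n_restarts_used = n_res,
                 pi = pi, par = best$par, kappa = exp(best$lk),
                 pat = pat, cs = cs, weights = w),
            class = "codon_fit")
}

.pairwise_pdist <- function(st) {
  n <- nrow(st)
  if (n < 2L) return(0.2)
  d <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(st[i, ]) & !is.na(st[j, ])
    if (any(ok)) d <- c(d, mean(st[i, ok] != st[j, ok]))
  }
  d
}

# free-ratio model: per-branch omega; coordinate optimization, sequential
# per-edge (t, omega) refinement after a global M0-style start
.fit_free_ratio <- function(pat, tree, pi, cs, kappa, el0, tol, w) {
  nedge <- nrow(tree$edge)
  lk <- log(kappa); lw <- rep(log(0.3), nedge); el <- el0
  lnL_of <- function(lk, lw, el) {
    # each edge its own class-free omega: use per-edge pruning via classes
    # trick: single class but omega varies by edge -> direct pruning
    .free_lnL(pat, tree, exp(lk), pi, exp(lw), el, cs, w)
  }
  lnL_prev <- -Inf; conv <- FALSE
  for (round in 1:8) {
    o1 <- optimize(function(v) -lnL_of(v, lw, el), c(log(0.2), log(20)))
    lk <- o1$minimum
    fn <- function(v) -lnL_of(lk, v[seq_len(nedge)],
                              exp(v[nedge + seq_len(nedge)]))
    o2 <- optim(c(lw, log(el)), fn, method = "L-BFGS-B",
                lower = c(rep(log(1e-4), nedge), rep(log(1e-7), nedge)),
                upper = c(rep(log(999), nedge), rep(log(20), nedge)),
                control = list(maxit = 200, factr = 1e4))
    lw <- o2$par[seq_len(nedge)]; el <- exp(o2$par[nedge + seq_len(nedge)])
    lnL <- -o2$value
    if (abs(lnL - lnL_prev) < tol) { conv <- TRUE; break }
    lnL_prev <- lnL
  }
  tree_out <- tree; tree_out$edge.length <- el
  pbo <- setNames(exp(lw), paste0("edge", seq_len(nedge)))
  structure(list(lnL = lnL, np = 2L * nedge + 1L,
                 mles = list(kappa = exp(lk)),
                 per_branch_omega = pbo, tree = tree_out, template = "free",
                 fg_edges = integer(0), converged = conv,
                 n_restarts_used = 1L, pi = pi, par = lw, kappa = exp(lk),
                 pat = pat, cs = cs, weights = w),
            class = "codon_fit")
}

# pruning with per-edge omega (free-ratio); eigen cache on omega values
.free_lnL <- function(pat, tree, kappa, pi, omega_edge, el, cs, w) {
  tre <- reorder(tree, "postorder")
  ord <- match(paste(tre$edge[, 1], tre$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  omega_edge <- omega_edge[ord]; el <- el[ord]
  edges <- tre$edge
  ntip <- length(tre$tip.label)
  tipidx <- match(tre$tip.label, rownames(pat$states))
  npat <- ncol(pat$states); K <- cs$K
  uw <- unique(round(omega_edge, 10))
  egs <- lapply(uw, function(x) codon_eigen(kappa, x, pi, cs))
  names(egs) <- as.character(uw)
  partial <- vector("list", ntip + tre$Nnode)
  logscale <- numeric(npat)
  for (e in seq_len(nrow(edges))) {
    P <- codon_P(egs[[as.character(round(omega_edge[e], 10))]], el[e])
    par <- edges[e, 1L]; child <- edges[e, 2L]
    if (child <= ntip) {
      stv <- pat$states[tipidx[child], ]
      contrib <- matrix(1, K, npat)
      ok <- !is.na(stv)
      if (any(ok)) contrib[, ok] <- P[, stv[ok], drop = FALSE]
    } else {
      cp <- partial[[child]]
      sc <- colSums(cp); sc[sc <= 0] <- 1
      logscale <- logscale + log(sc)
      contrib <- P %*% (cp / rep(sc, each = K))
    }
    partial[[par]] <- if (is.null(partial[[par]])) contrib else
      partial[[par]] * contrib
  }
  root <- edges[nrow(edges), 1L]
  lik <- colSums(pi * partial[[root]])
  sum(w * (log(pmax(lik, 1e-300)) + logscale))
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("codon model %s: lnL = %.4f (np = %d, converged = %s)\n",
              x$template, x$lnL, x$np, x$converged))
  if (length(x$mles)) {
    flat <- unlist(x$mles)
    cat("  ", paste(sprintf("%s = %.4g", names(flat), flat),
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' Likelihood-ratio test between nested codon models
#'
#' `2dL = 2 (lnL_alt - lnL_null)`; p from the chi-squared distribution with
#' `df` degrees of freedom, or from the 50:50 mixture of a point mass at zero
#' and chi-squared(df) when `boundary_mixture` (the branch-site test, where
#' the foreground omega2 = 1 sits on the boundary).  A negative statistic
#' beyond `tolerance` triggers an optimizer warning and is reported as-is
#' with `p = NA`.
#'
#' @param lnL_null,lnL_alt maximized log-likelihoods (alt nests null).
#' @param df degrees of freedom.
#' @param boundary_mixture use the 0.5 chi2_0 + 0.5 chi2_df null.
#' @param tolerance allowed negative slack before warning.
#' @return list with `two_delta_L`, `p`, `p_chisq`, `p_mixture`, `df`.
#' @export
lrt <- function(lnL_null, lnL_alt, df = 1L, boundary_mixture = FALSE,
                tolerance = 1e-4) {
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < -tolerance) {
    warning(sprintf(
      "optimizer-warning: 2dL = %.4f < 0; alternative fit worse than null",
      stat))
    return(list(two_delta_L = stat, p = NA_real_, p_chisq = NA_real_,
                p_mixture = NA_real_, df = df))
  }
  s <- max(stat, 0)
  p_chisq <- pchisq(s, df, lower.tail = FALSE)
  p_mix <- if (s == 0) 1 else 0.5 * pchisq(s, df, lower.tail = FALSE)
  list(two_delta_L = stat,
       p = if (boundary_mixture) p_mix else p_chisq,
       p_chisq = p_chisq, p_mixture = p_mix, df = df)
}

#' Naive empirical Bayes site posteriors for the positive-selection class
#'
#' Posterior of class c at site s is `p_c L_s(c) / sum_c' p_c' L_s(c')`; the
#' positive-selection probability sums the classes with foreground omega > 1.
#' For a site identical across taxa the posterior equals the prior class
#' proportions.
#'
#' @param fit a [fit_model()] result for M2a, M8 or bsA (any template with a
#'   class of omega > 1).
#' @param threshold flagging threshold (default 0.95).
#' @return object of class `site_posterior`: data.frame with `site`,
#'   `p_positive`, `flagged`, plus the full class-posterior matrix as
#'   attribute `"class_posterior"`.
#' @export
site_posteriors <- function(fit, threshold = 0.95) {
  stopifnot(inherits(fit, "codon_fit"))
  tmpl <- .template(fit$template)
  classes <- tmpl$classes(fit$par, fit$fg_edges)
  props <- vapply(classes, `[[`, 0, "prop")
  wfg <- vapply(classes, `[[`, 0, "w_fg")
  pos_class <- wfg > 1
  if (!any(pos_class))
    stop("input-error: no positive-selection class in template ", fit$template)
  ll <- codon_site_lik(fit$pat, fit$tree, fit$kappa, fit$pi, classes,
                       fit$fg_edges, fit$cs)
  m <- apply(ll, 1L, max)
  lik <- exp(ll - m) * rep(props, each = nrow(ll))
  post <- lik / rowSums(lik)
  post_full <- post[fit$pat$map, , drop = FALSE]
  p_pos <- rowSums(post_full[, pos_class, drop = FALSE])
  out <- data.frame(site = seq_along(p_pos), p_positive = p_pos,
                    flagged = p_pos >= threshold)
  attr(out, "class_posterior") <- post_full
  class(out) <- c("site_posterior", class(out))
  out
}
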