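# Ground-truth generators: Yule/birth-death trees, duplication gene trees,
# Gillespie-simulated codon alignments with per-branch and per-site-class
# omega, and radical-biased two-clade protein alignments.  Every generator is
# a pure function of (parameters, seed).

#' Simulate an ultrametric tree under a Yule or birth-death process
#'
#' Forward simulation conditioned on exactly `n` extant tips: lineages split
#' at rate `birth` and die at rate `death`; simulation restarts (up to
#' `max_retries`) when the process dies out or overshoots.  For the Yule
#' case the waiting time with k lineages is exponential with rate
#' `k * birth`, and an additional exponential interval with n lineages is
#' appended before the present.
#'
#' @param kind `"yule"` or `"birth-death"`.
#' @param n number of extant tips (>= 3).
#' @param birth speciation rate (> 0).
#' @param death extinction rate (>= 0; `"yule"` forces 0).
#' @param seed integer seed (required for reproducibility).
#' @param max_retries restarts allowed before a simulation-error.
#' @return an ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(kind = c("yule", "birth-death"), n, birth = 1,
                          death = 0, seed = NULL, max_retries = 1000L) {
  kind <- match.arg(kind)
  stopifnot(n >= 3L, birth > 0, death >= 0)
  if (kind == "yule") death <- 0
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    # forward simulation: active lineages with birth times of their pending
    # branch; build edge list incrementally
    tr <- .bd_forward(n, birth, death)
    if (!is.null(tr)) return(tr)
  }
  stop("simulation-error: could not condition on ", n,
       " tips after ", max_retries, " attempts")
}

.bd_forward <- function(n, birth, death) {
  # node bookkeeping: grow a table of (parent, time_of_birth); active =
  # indices of currently alive lineages
  parent <- c(NA_integer_, 1L, 1L)     # 1 = root with two children
  btime <- c(0, 0, 0)
  active <- c(2L, 3L)
  now <- 0
  while (length(active) > 0L && length(active) < n) {
    k <- length(active)
    now <- now + rexp(1L, k * (birth + death))
    i <- sample(k, 1L)
    if (runif(1L) < birth / (birth + death)) {
      id <- active[i]
      new1 <- length(parent) + 1L; new2 <- new1 + 1L
      parent <- c(parent, id, id); btime <- c(btime, now, now)
      active <- c(active[-i], new1, new2)
    } else {
      active <- active[-i]             # extinction: prune the whole lineage
    }
  }
  if (length(active) != n) return(NULL)
  now <- now + rexp(1L, n * (birth + death))  # final interval to the present
  # assemble a phylo: tips = active lineages at `now`; interior nodes =
  # lineages with both children sampled (extinct subtrees pruned)
  nlin <- length(parent)
  is_tip <- seq_len(nlin) %in% active
  # keep only lineages with extant descendants
  keep <- is_tip
  for (i in rev(seq_len(nlin))) if (keep[i] && !is.na(parent[i]))
    keep[parent[i]] <- TRUE
  # collapse single-child chains (from pruned extinct subtrees) and build
  # the newick recursively; a lineage's branch runs from its birth (parent
  # split, t0) to its own split (btime of its children) or to the present
  alive_kids <- function(i) which(keep & parent == i)
  tipc <- 0L
  build <- function(i, t0) {
    kids <- alive_kids(i)
    while (!is_tip[i] && length(kids) == 1L) {   # pass-through node
      i <- kids
      kids <- alive_kids(i)
    }
    if (is_tip[i]) {
      tipc <<- tipc + 1L
      return(sprintf("t%d:%.10f", tipc, now - t0))
    }
    split_t <- btime[kids[1L]]
    sub <- vapply(kids, function(kid) build(kid, split_t), "")
    sprintf("(%s):%.10f", paste(sub, collapse = ","), split_t - t0)
  }
  core <- build(1L, 0)
  nwk <- paste0(sub(":[0-9.eE+-]+$", "", core), ";")   # no root edge
  tr <- tryCatch(ape::read.tree(text = nwk), error = function(e) NULL)
  if (is.null(tr) || length(tr$tip.label) != n) return(NULL)
  tr
}

#' Duplication scenario description
#'
#' @param n_species number of species.
#' @param placement `"before-speciation"` (one duplication at the root of two
#'   mirrored species clades) or `"after-speciation"` (species-local
#'   duplicate pairs).
#' @param birth speciation rate of the species tree.
#' @param dup_branch branch length of the duplication stem(s).
#' @return a `dup_scenario` list.
#' @export
dup_scenario <- function(n_species, placement = c("before-speciation",
                                                  "after-speciation"),
                         birth = 1, dup_branch = 0.2) {
  placement <- match.arg(placement)
  stopifnot(n_species >= 3L)
  structure(list(n_species = as.integer(n_species), placement = placement,
                 birth = birth, dup_branch = dup_branch),
            class = "dup_scenario")
}

#' Simulate a duplication gene tree
#'
#' Tips are labeled `<species>_dup1` / `<species>_dup2`.  Under
#' before-speciation, the duplication sits at the root of two mirrored
#' species clades; under after-speciation each species' two copies are
#' sisters at the tips of the species tree.
#'
#' @param scenario a [dup_scenario()].
#' @param seed integer seed.
#' @return a rooted `phylo` gene tree.
#' @export
simulate_duplication_gene_tree <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "dup_scenario"))
  if (!is.null(seed)) set.seed(seed)
  sp <- simulate_tree("yule", scenario$n_species, scenario$birth)
  sp$tip.label <- paste0("sp", seq_len(scenario$n_species))
  if (scenario$placement == "before-speciation") {
    t1 <- sp; t1$tip.label <- paste0(sp$tip.label, "_dup1")
    t2 <- sp; t2$tip.label <- paste0(sp$tip.label, "_dup2")
    t1$root.edge <- NULL; t2$root.edge <- NULL
    nw <- sprintf("(%s:%.8f,%s:%.8f);",
                  sub(";$", "", write_newick(t1)), scenario$dup_branch,
                  sub(";$", "", write_newick(t2)), scenario$dup_branch)
    ape::read.tree(text = nw)
  } else {
    # replace each species tip by a cherry of its two copies
    nw <- write_newick(sp)
    for (s in sp$tip.label) {
      nw <- sub(paste0("\\b", s, ":"),
                sprintf("(%s_dup1:%.8f,%s_dup2:%.8f):",
                        s, scenario$dup_branch, s, scenario$dup_branch),
                nw)
    }
    ape::read.tree(text = nw)
  }
}

#' Simulate a codon alignment along a tree (Gillespie)
#'
#' Root codons are drawn from the equilibrium frequencies; each site evolves
#' along every branch by exact stochastic simulation of the 61-state process
#' under its site class (background/foreground omega per branch), so realized
#' substitution counts are available as ground truth.
#'
#' @param tree `phylo` with branch lengths (expected substitutions per codon
#'   site at equilibrium).
#' @param n_codons number of codon sites.
#' @param kappa transition/transversion ratio.
#' @param classes site-class list as in [site_log_likelihoods()]; default one
#'   neutral class.  Site classes are assigned i.i.d. by their proportions.
#' @param omega shortcut for a single-ratio simulation.
#' @param fg_edges foreground edge indices (rows of `tree$edge`).
#' @param pi codon equilibrium frequencies (61), default equal.
#' @param seed integer seed.
#' @param code a [genetic_code()].
#' @return list with `ca` (codon alignment), `record` (per-branch realized
#'   syn/nonsyn counts), `site_class` (true class per site), `seed`.
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2, omega = NULL,
                                     classes = NULL, fg_edges = integer(0),
                                     pi = NULL, seed = NULL,
                                     code = genetic_code()) {
  if (!is.null(seed)) set.seed(seed)
  cs <- codon_setup(code)
  if (is.null(pi)) pi <- rep(1 / cs$K, cs$K)
  if (is.null(classes)) {
    if (is.null(omega)) omega <- 1
    classes <- list(list(prop = 1, w_bg = omega, w_fg = omega))
  }
  props <- vapply(classes, `[[`, 0, "prop"); props <- props / sum(props)
  site_class <- sample.int(length(classes), n_codons, replace = TRUE,
                           prob = props)
  omegas <- unique(unlist(lapply(classes, function(cl) c(cl$w_bg, cl$w_fg))))
  egs <- lapply(omegas, function(wv) codon_eigen(kappa, wv, pi, cs))
  names(egs) <- as.character(omegas)
  Qs <- lapply(egs, `[[`, "Q")
  rate_of <- function(wv) egs[[as.character(wv)]]$rate_raw
  # common time scale across classes (branch length = expected subs per
  # codon site averaged over classes, per branch regime)
  mean_rate_bg <- sum(props * vapply(vapply(classes, `[[`, 0, "w_bg"),
                                     rate_of, 0))
  mean_rate_fg <- sum(props * vapply(vapply(classes, `[[`, 0, "w_fg"),
                                     rate_of, 0))
  tre <- reorder(tree, "postorder")
  edges <- tre$edge; el <- tre$edge.length
  ntip <- length(tre$tip.label)
  root <- edges[nrow(edges), 1L]
  nnode <- ntip + tre$Nnode
  states <- matrix(NA_integer_, nnode, n_codons)
  states[root, ] <- sample.int(cs$K, n_codons, replace = TRUE, prob = pi)
  # fg_edges index rows of the ORIGINAL tree$edge; remap to postorder
  ord_orig <- match(paste(edges[, 1L], edges[, 2L]),
                    paste(tree$edge[, 1L], tree$edge[, 2L]))
  is_fg <- ord_orig %in% fg_edges
  rec <- data.frame(edge = seq_len(nrow(edges)),
                    parent = edges[, 1L], child = edges[, 2L],
                    n_syn = 0L, n_nonsyn = 0L)
  syn_type <- cs$type == 1L | cs$type == 2L
  # preorder traversal = reverse postorder
  for (e in rev(seq_len(nrow(edges)))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    for (s in seq_len(n_codons)) {
      cl <- classes[[site_class[s]]]
      wv <- if (is_fg[e]) cl$w_fg else cl$w_bg
      Q <- Qs[[as.character(wv)]]
      rel <- rate_of(wv) / if (is_fg[e]) mean_rate_fg else mean_rate_bg
      x <- states[par, s]; t_left <- el[e] * rel
      repeat {
        rate <- -Q[x, x]
        if (rate <= 0) break
        dt <- rexp(1L, rate)
        if (dt > t_left) break
        t_left <- t_left - dt
        probs <- Q[x, ]; probs[x] <- 0
        y <- sample.int(cs$K, 1L, prob = probs)
        if (syn_type[x, y]) rec$n_syn[e] <- rec$n_syn[e] + 1L else
          rec$n_nonsyn[e] <- rec$n_nonsyn[e] + 1L
        x <- y
      }
      states[child, s] <- x
    }
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L, function(r)
    paste(cs$sense[r], collapse = ""))
  a <- aln(seqs, ids = tre$tip.label)
  ca <- to_codon_alignment(a, code)
  list(ca = ca, record = rec, site_class = site_class, seed = seed,
       tree = tre)
}

#' Simulate a radical-biased two-clade protein alignment
#'
#' At a chosen fraction of sites the two clade ancestors are forced into
#' different charge classes (a type-II divergence construct); at the
#' remaining sites they share the ancestral residue.  Tips add independent
#' within-clade substitution noise at a low per-site rate.
#'
#' @param n_sites alignment length (e.g. 255).
#' @param divergent_fraction fraction of sites forced radical between clades.
#' @param n_per_clade sequences per clade (>= 3).
#' @param noise_rate per-site within-clade substitution probability per tip.
#' @param seed integer seed.
#' @return list with `aln` (protein [aln()]), `tips1`, `tips2`,
#'   `truth` (logical per site: TRUE = divergent), `anc1`, `anc2`.
#' @export
simulate_radical_bias <- function(n_sites = 255L, divergent_fraction = 0.1,
                                  n_per_clade = 5L, noise_rate = 0.02,
                                  seed = NULL) {
  stopifnot(divergent_fraction >= 0, divergent_fraction <= 1,
            n_per_clade >= 3L)
  if (!is.null(seed)) set.seed(seed)
  aas <- .AA20
  anc <- sample(aas, n_sites, replace = TRUE)
  ndiv <- round(divergent_fraction * n_sites)
  div_sites <- if (ndiv > 0) sample.int(n_sites, ndiv) else integer(0)
  truth <- rep(FALSE, n_sites); truth[div_sites] <- TRUE
  anc1 <- anc; anc2 <- anc
  for (s in div_sites) {
    cls <- .aa_charge[anc[s]]
    other <- aas[.aa_charge[aas] != cls]
    anc2[s] <- sample(other, 1L)
  }
  mk_clade <- function(ancv, tag) {
    m <- matrix(rep(ancv, n_per_clade), nrow = n_per_clade, byrow = TRUE)
    for (i in seq_len(n_per_clade)) {
      hits <- which(runif(n_sites) < noise_rate)
      if (length(hits))
        m[i, hits] <- vapply(m[i, hits], function(a)
          sample(setdiff(aas, a), 1L), "")
    }
    rownames(m) <- paste0(tag, seq_len(n_per_clade))
    m
  }
  m <- rbind(mk_clade(anc1, "c1_"), mk_clade(anc2, "c2_"))
  list(aln = aln(m, type = "protein"),
       tips1 = paste0("c1_", seq_len(n_per_clade)),
       tips2 = paste0("c2_", seq_len(n_per_clade)),
       truth = truth, anc1 = anc1, anc2 = anc2)
}
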