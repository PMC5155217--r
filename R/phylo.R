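# Distance-based trees (including synonymous-only and nonsynonymous-only
# Nei-Gojobori distances), lineage-through-time curves and the
# Pybus-Harvey gamma-statistic of diversification-rate variation.

#' Pairwise distance matrix
#'
#' `p` is the proportion of differing (mutually non-missing) sites; `JC69`
#' and `K2P` apply the standard corrections; `NG-syn`/`NG-nonsyn` are the
#' Nei-Gojobori proportions pS / pN (synonymous differences per synonymous
#' site and the nonsynonymous analogue) and require a codon alignment.
#' Saturated corrections (log of a non-positive number) are flagged `NA` with
#' a warning rather than an error.
#'
#' @param x an [aln()] (or codon alignment for the NG methods).
#' @param method one of `"p"`, `"JC69"`, `"K2P"`, `"NG-syn"`, `"NG-nonsyn"`.
#' @param code genetic code for the NG methods.
#' @return a `dist_matrix`: symmetric matrix with `method` attribute.
#' @export
distance_matrix <- function(x, method = c("p", "JC69", "K2P", "NG-syn",
                                          "NG-nonsyn"),
                            code = genetic_code()) {
  method <- match.arg(method)
  if (method %in% c("NG-syn", "NG-nonsyn")) {
    ca <- if (inherits(x, "codon_aln")) x else to_codon_alignment(x, code)
    cods <- codon_strings(ca)
    n <- nrow(cods); ids <- rownames(cods)
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ng <- ng86_counts(cods[i, ], cods[j, ], code)
      D[i, j] <- D[j, i] <- if (method == "NG-syn") ng$pS else ng$pN
    }
  } else {
    m <- unclass(if (inherits(x, "codon_aln")) x$aln else x)
    n <- nrow(m); ids <- rownames(m)
    good <- matrix(m %in% c("A", "C", "G", "T"), n)
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- good[i, ] & good[j, ]
      if (!any(ok)) { D[i, j] <- D[j, i] <- NA_real_; next }
      a <- m[i, ok]; b <- m[j, ok]
      p <- mean(a != b)
      d <- switch(method,
        p = p,
        JC69 = if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3),
        K2P = {
          ts <- mean((a == "A" & b == "G") | (a == "G" & b == "A") |
                     (a == "C" & b == "T") | (a == "T" & b == "C"))
          tv <- p - ts
          w1 <- 1 - 2 * ts - tv; w2 <- 1 - 2 * tv
          if (w1 <= 0 || w2 <= 0) NA_real_ else
            -0.5 * log(w1) - 0.25 * log(w2)
        })
      D[i, j] <- D[j, i] <- d
    }
  }
  if (anyNA(D)) warning("saturation: some pairwise corrections undefined (NA)")
  structure(D, method = method, class = c("dist_matrix", "matrix"))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei NJ (via ape's implementation) with deterministic tie-breaking
#' by label order; negative branch lengths are clamped to zero with the
#' deficit moved to the sister branch so path lengths are preserved.
#'
#' @param dm a [distance_matrix()] (or any labeled symmetric matrix).
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  labs <- rownames(dm)
  if (length(labs) < 3L) stop("input-error: NJ needs at least 3 taxa")
  o <- order(labs)
  m <- unclass(dm)[o, o]
  class(m) <- "matrix"
  tr <- ape::nj(as.dist(m))
  # clamp negatives, moving the deficit to the sister branch
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    sisters <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sisters))
      tr$edge.length[sisters[1L]] <-
        max(0, tr$edge.length[sisters[1L]] + deficit)
  }
  tr
}

#' Make a tree ultrametric by node-depth averaging
#'
#' Roots an unrooted tree at its midpoint (unless already rooted or an
#' outgroup is given) and sets every internal node's age to the mean of the
#' node-to-tip path lengths below it, clamping child ages below parent ages.
#' This is a rate-smoothing-free ultrametricization appropriate for trees
#' whose branch lengths are proportions of substitutions.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param outgroup optional tip label(s) to root on (outgroup is removed
#'   after rooting when `drop_outgroup = TRUE`).
#' @param drop_outgroup drop the outgroup tips after rooting.
#' @return a rooted ultrametric `phylo` tree.
#' @export
make_ultrametric <- function(tree, outgroup = NULL, drop_outgroup = FALSE) {
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    if (drop_outgroup) tree <- ape::drop.tip(tree, outgroup)
  } else if (!ape::is.rooted(tree)) {
    tree <- tryCatch(phangorn::midpoint(tree), error = function(e)
      ape::root(tree, tree$tip.label[1L], resolve.root = TRUE))
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # mean node-to-tip distance per internal node
  dm <- ape::dist.nodes(tree)
  ages <- numeric(ntip + nnode)
  for (nd in (ntip + 1L):(ntip + nnode)) {
    tips <- .tips_below(tree, nd)
    ages[nd] <- mean(dm[nd, tips])
  }
  # enforce parent age > child age (top-down), then rebuild edge lengths
  tre <- reorder(tree, "postorder")
  edges_root_first <- tre$edge[rev(seq_len(nrow(tre$edge))), , drop = FALSE]
  for (r in seq_len(nrow(edges_root_first))) {
    par <- edges_root_first[r, 1L]; child <- edges_root_first[r, 2L]
    if (child > ntip)
      ages[child] <- min(ages[child], ages[par] * 0.9999)
  }
  out <- tree
  out$edge.length <- ages[tree$edge[, 1L]] -
    ifelse(tree$edge[, 2L] > ntip, ages[tree$edge[, 2L]], 0)
  out$edge.length <- pmax(out$edge.length, 0)
  out
}

.tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0); stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

# internode intervals g_k (duration with k lineages, k = 2..n) of a rooted
# ultrametric tree
.internode_intervals <- function(tree) {
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)   # distance from root
  node_depths <- sort(depths[(ntip + 1L):(ntip + tree$Nnode)])
  total <- max(depths)
  events <- c(node_depths, total)              # root at 0 .. present
  g <- diff(c(events))                         # intervals between splits
  # g[k-1] = duration with k lineages, k = 2..n
  g
}

#' Pybus-Harvey gamma-statistic
#'
#' With internode intervals `g_k` (duration during which the reconstructed
#' tree has k lineages, k = 2..n) and `T = sum k g_k`,
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\sum_{k=2}^{i} k g_k -
#'   T/2}{T\sqrt{1/(12(n-2))}}}
#' Under a constant-rate pure-birth process gamma is standard normal;
#' positive values indicate a late acceleration of diversification.
#' Non-ultrametric trees are first made ultrametric via
#' [make_ultrametric()] (disable with `ultrametricize = FALSE` to use raw
#' node depths).
#'
#' @param tree rooted tree with >= 3 tips.
#' @param ultrametricize apply [make_ultrametric()] when the tree is not
#'   ultrametric (default TRUE).
#' @param outgroup optional outgroup passed to [make_ultrametric()].
#' @return list with `gamma`, `p` (two-sided normal), `n`.
#' @export
gamma_statistic <- function(tree, ultrametricize = TRUE, outgroup = NULL) {
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("input-error: gamma requires >= 3 tips")
  if (ultrametricize &&
      (!ape::is.rooted(tree) || !ape::is.ultrametric(tree, tol = 1e-8)))
    tree <- make_ultrametric(tree, outgroup = outgroup,
                             drop_outgroup = !is.null(outgroup))
  n <- length(tree$tip.label)
  g <- .internode_intervals(tree)
  k <- 2:n
  if (length(g) != n - 1L)
    stop("input-error: tree is not binary-resolvable for gamma")
  kg <- k * g
  T_tot <- sum(kg)
  if (T_tot <= 0) return(list(gamma = NA_real_, p = NA_real_, n = n))
  cum <- cumsum(kg)                     # sum_{k=2..i} k g_k at i = 2..n
  num <- mean(cum[seq_len(n - 2L)]) - T_tot / 2
  gamma <- num / (T_tot * sqrt(1 / (12 * (n - 2))))
  list(gamma = gamma, p = 2 * pnorm(-abs(gamma)), n = n)
}

#' Lineage-through-time curve
#'
#' Sorted node depths of a rooted tree with the number of reconstructed
#' lineages through (relative) time.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param relative rescale depths to \[0, 1\] ("proportion of substitutions"
#'   time axis).
#' @return data.frame with `time` and `lineages` (2 at the root, n at the
#'   present).
#' @export
ltt_curve <- function(tree, relative = TRUE) {
  if (!ape::is.rooted(tree)) stop("input-error: LTT requires a rooted tree")
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  nd <- sort(depths[(ntip + 1L):(ntip + tree$Nnode)])
  total <- max(depths)
  tm <- c(nd, total)
  if (relative && total > 0) tm <- tm / total
  data.frame(time = tm, lineages = c(seq.int(2L, length.out = length(nd)),
                                     ntip))
}
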