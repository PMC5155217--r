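# Coalescent simulation conditioned on a fixed number of segregating sites,
# with no recombination, free recombination (independent-site genealogies) or
# a per-gene recombination rate rho (discrete-site ancestral recombination
# graph).  Produces the null distributions behind the recombination table.

#' Coalescent simulation configuration
#'
#' @param n sample size (>= 2; at most 52 in mode `"rho"`).
#' @param S fixed number of segregating sites (>= 0); every replicate carries
#'   exactly S sites (DnaSP-style fixed-S conditioning).
#' @param recomb_mode `"none"`, `"free"`, or `"rho"`.
#' @param rho per-gene population recombination rate (mode `"rho"` only).
#' @param L number of sites for mode `"rho"` (breakpoints fall between them).
#' @param reps replicate count for [null_distribution()].
#' @param seed integer RNG seed; required for reproducible pipeline runs.
#' @return a `coal_config` list.
#' @export
coal_config <- function(n, S, recomb_mode = c("none", "free", "rho"),
                        rho = 0, L = 1000L, reps = 1000L, seed = NULL) {
  recomb_mode <- match.arg(recomb_mode)
  stopifnot(n >= 2L, S >= 0L, reps >= 1L, rho >= 0)
  structure(list(n = as.integer(n), S = as.integer(S),
                 recomb_mode = recomb_mode, rho = rho, L = as.integer(L),
                 reps = as.integer(reps), seed = seed),
            class = "coal_config")
}

# one Kingman n-coalescent: returns list(tipsets = lineage tip-set list,
# lengths = matching branch lengths, n).
.kingman_tree <- function(n) {
  lens <- numeric(0); branches <- list()
  lineage_sets <- as.list(seq_len(n))
  birth <- rep(0, n)
  alive <- seq_len(n)
  now <- 0; k <- n
  while (k > 1L) {
    now <- now + rexp(1L, k * (k - 1) / 2)
    pair <- sample(alive, 2L)
    for (id in pair) {
      branches[[length(branches) + 1L]] <- lineage_sets[[id]]
      lens <- c(lens, now - birth[id])
    }
    new_id <- length(lineage_sets) + 1L
    lineage_sets[[new_id]] <- sort(c(lineage_sets[[pair[1L]]],
                                     lineage_sets[[pair[2L]]]))
    birth[new_id] <- now
    alive <- c(setdiff(alive, pair), new_id)
    k <- k - 1L
  }
  list(tipsets = branches, lengths = lens, n = n)
}

# place S mutations on a genealogy proportionally to branch length; returns
# n x S 0/1 matrix (derived allele = tips below the mutated branch)
.drop_mutations <- function(tree, S) {
  n <- tree$n
  if (S == 0L) return(matrix(integer(0), nrow = n, ncol = 0))
  b <- sample.int(length(tree$lengths), S, replace = TRUE,
                  prob = tree$lengths)
  out <- matrix(0L, n, S)
  for (s in seq_len(S)) out[tree$tipsets[[b[s]]], s] <- 1L
  out
}

# --- discrete-site ARG -------------------------------------------------------
# A lineage is a run matrix with columns (start, end, mask): at sites in
# [start, end] it is ancestral to the tips set in `mask` (bitmask as double;
# masks at a given site are disjoint across lineages, so OR == sum).  Runs
# with mask == full (MRCA reached) are removed as soon as they appear.

.runs_split <- function(runs, brk) {
  # split into sites <= brk and sites > brk
  left <- runs[runs[, 1L] <= brk, , drop = FALSE]
  right <- runs[runs[, 2L] > brk, , drop = FALSE]
  if (nrow(left)) left[left[, 2L] > brk, 2L] <- brk
  if (nrow(right)) right[right[, 1L] <= brk, 1L] <- brk + 1
  list(left, right)
}

.runs_merge <- function(a, b, full) {
  # piecewise union of two disjoint-mask run lists; returns list(runs,
  # n_coalesced = number of sites whose merged mask reached `full`)
  bounds <- sort(unique(c(a[, 1L], a[, 2L] + 1, b[, 1L], b[, 2L] + 1)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L] - 1
  mask_at <- function(runs, s) {
    i <- which(runs[, 1L] <= s & runs[, 2L] >= s)
    if (length(i)) runs[i[1L], 3L] else 0
  }
  m <- vapply(starts, function(s) mask_at(a, s) + mask_at(b, s), 0)
  keep <- m != 0 & m != full
  ncoal <- sum((ends - starts + 1)[m == full])
  runs <- cbind(start = starts[keep], end = ends[keep], mask = m[keep])
  # merge adjacent runs with equal masks
  if (nrow(runs) > 1L) {
    out <- runs[1L, , drop = FALSE]
    for (r in 2L:nrow(runs)) {
      if (runs[r, 3L] == out[nrow(out), 3L] &&
          runs[r, 1L] == out[nrow(out), 2L] + 1) {
        out[nrow(out), 2L] <- runs[r, 2L]
      } else out <- rbind(out, runs[r, , drop = FALSE])
    }
    runs <- out
  }
  list(runs = runs, n_coalesced = ncoal)
}

.mask_to_tips <- function(mask, n) {
  which((mask %/% 2^(seq_len(n) - 1)) %% 2 == 1)
}

# simulate the ARG; returns record matrix (start, end, dur, mask) of marginal
# branch segments with proper nonempty tip sets
.arg_sim <- function(n, rho, L) {
  stopifnot(n <= 52L)
  full <- sum(2^(seq_len(n) - 1))
  lineages <- lapply(seq_len(n), function(i)
    cbind(start = 1, end = L, mask = 2^(i - 1)))
  uncoal <- L
  rec <- matrix(0, 4096L, 4L)
  colnames(rec) <- c("start", "end", "dur", "mask")
  nrec <- 0L
  push <- function(rows) {
    nr <- nrow(rows)
    while (nrec + nr > nrow(rec)) {
      rec <<- rbind(rec, matrix(0, nrow(rec), 4L))
    }
    rec[(nrec + 1L):(nrec + nr), ] <<- rows
    nrec <<- nrec + nr
  }
  while (uncoal > 0L && length(lineages) > 1L) {
    k <- length(lineages)
    spans <- vapply(lineages, function(r)
      max(0, (max(r[, 2L]) - min(r[, 1L])) / max(1L, L - 1L)), 0)
    rate_c <- k * (k - 1) / 2
    rate_r <- rho * sum(spans)
    dt <- rexp(1L, rate_c + rate_r)
    for (r in lineages) push(cbind(r[, 1L], r[, 2L], dt, r[, 3L]))
    if (runif(1L) < rate_c / (rate_c + rate_r)) {
      pair <- sample.int(k, 2L)
      mg <- .runs_merge(lineages[[pair[1L]]], lineages[[pair[2L]]], full)
      uncoal <- uncoal - mg$n_coalesced
      lineages <- lineages[-pair]
      if (nrow(mg$runs)) lineages <- c(lineages, list(mg$runs))
    } else {
      li <- sample.int(k, 1L, prob = spans)
      r <- lineages[[li]]
      lo <- min(r[, 1L]); hi <- max(r[, 2L])
      brk <- if (hi - 1 >= lo) sample(seq(lo, hi - 1), 1L) else lo
      parts <- .runs_split(r, brk)
      parts <- parts[vapply(parts, nrow, 0L) > 0L]
      lineages <- c(lineages[-li], parts)
    }
  }
  list(rec = rec[seq_len(nrec), , drop = FALSE], n = n, L = L)
}

#' Simulate one coalescent sample with a fixed number of segregating sites
#'
#' Mode `"none"` draws one standard n-coalescent genealogy and places S
#' mutations on branches with probability proportional to branch length, each
#' at a distinct site.  Mode `"free"` draws every site on an independent
#' genealogy (complete linkage equilibrium).  Mode `"rho"` runs a
#' discrete-site ancestral recombination graph across `L` sites and places S
#' mutations on the marginal trees (`rho = 0` is equivalent in distribution
#' to mode `"none"`).
#'
#' @param cfg a [coal_config()].
#' @return a `segsites` object (all sites biallelic).
#' @export
simulate_sample <- function(cfg) {
  stopifnot(inherits(cfg, "coal_config"))
  n <- cfg$n; S <- cfg$S
  states <- switch(cfg$recomb_mode,
    none = .drop_mutations(.kingman_tree(n), S),
    free = {
      if (S == 0L) matrix(integer(0), n, 0) else
        do.call(cbind, lapply(seq_len(S), function(s)
          .drop_mutations(.kingman_tree(n), 1L)))
    },
    rho = {
      if (cfg$rho == 0) .drop_mutations(.kingman_tree(n), S) else {
        arg <- .arg_sim(n, cfg$rho, cfg$L)
        sites <- sort(sample.int(cfg$L, min(S, cfg$L)))
        cols <- matrix(0L, n, length(sites))
        for (i in seq_along(sites)) {
          s <- sites[i]
          hit <- arg$rec[, 1L] <= s & arg$rec[, 2L] >= s
          dur <- arg$rec[hit, 3L]
          seg <- if (length(dur) == 1L) 1L else
            sample.int(length(dur), 1L, prob = dur)
          tips <- .mask_to_tips(arg$rec[hit, 4L][seg], n)
          cols[tips, i] <- 1L
        }
        cols
      }
    })
  L <- max(cfg$L, S)
  pos <- sort(sample.int(L, S))
  rownames(states) <- paste0("hap", seq_len(n))
  structure(list(positions = pos, states = states, n = n, S = S,
                 multiallelic_positions = integer(0), L = L),
            class = "segsites")
}

#' Monte-Carlo null distribution of a statistic
#'
#' Runs `cfg$reps` coalescent replicates, evaluates `statistic` on each
#' simulated `segsites`, and summarizes the null distribution with mean,
#' 2.5/97.5 percentile CI and empirical p-values.  `p_ge` uses the
#' Davison-Hinkley add-one correction `(#\{sim >= obs\} + 1)/(reps + 1)` so
#' p is never exactly 0; the raw proportions are reported alongside.
#' Replicates on which the statistic is undefined (`NA`) are dropped and
#' counted; a warning is issued if more than 10% drop.
#'
#' @param cfg a [coal_config()]; `cfg$seed`, when non-NULL, makes the result
#'   bit-identical across calls.
#' @param statistic function `segsites -> numeric(1)`.
#' @param observed observed value of the statistic.
#' @param name statistic name for printing.
#' @return object of class `null_dist`: list with `statistic`, `samples`,
#'   `mean`, `ci_low`, `ci_high`, `p_ge`, `p_le`, `p_ge_raw`, `p_le_raw`,
#'   `observed`, `n_dropped`.
#' @export
null_distribution <- function(cfg, statistic, observed, name = "statistic") {
  stopifnot(inherits(cfg, "coal_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  vals <- vapply(seq_len(cfg$reps), function(i) {
    v <- statistic(simulate_sample(cfg))
    if (is.null(v) || !is.finite(v)) NA_real_ else as.numeric(v)
  }, 0)
  dropped <- sum(is.na(vals))
  if (dropped > 0.1 * cfg$reps)
    warning(sprintf("%d/%d replicates dropped (statistic undefined)",
                    dropped, cfg$reps))
  v <- vals[!is.na(vals)]
  reps <- length(v)
  structure(list(
    statistic = name, samples = v, mean = mean(v),
    ci_low = unname(quantile(v, 0.025, type = 7)),
    ci_high = unname(quantile(v, 0.975, type = 7)),
    p_ge = (sum(v >= observed) + 1) / (reps + 1),
    p_le = (sum(v <= observed) + 1) / (reps + 1),
    p_ge_raw = mean(v >= observed),
    p_le_raw = mean(v <= observed),
    observed = observed, n_dropped = dropped), class = "null_dist")
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf(
    "null distribution of %s: observed %.4g; mean %.4g [%.4g, %.4g]; P(sim >= obs) = %.4g\n",
    x$statistic, x$observed, x$mean, x$ci_low, x$ci_high, x$p_ge))
  invisible(x)
}

# convert simulated segsites to a 2-state DNA alignment ("A"/"T") so that
# alignment-level statistics (pi, Tajima's D, Hudson's R) can run on it
#' Convert simulated segregating sites to a two-state DNA alignment
#'
#' Sites are written at their sampled positions within an `L`-site background
#' of monomorphic "A"; the derived allele is "T".
#' @param ss a `segsites` object.
#' @return an [aln()].
#' @export
segsites_to_aln <- function(ss) {
  m <- matrix("A", ss$n, ss$L)
  if (length(ss$positions))
    m[, ss$positions] <- ifelse(ss$states == 1L, "T", "A")
  rownames(m) <- rownames(ss$states) %||% paste0("hap", seq_len(ss$n))
  aln(m, ids = rownames(m))
}
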