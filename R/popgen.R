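# Diversity, neutrality and recombination statistics on an alignment.
# All statistics mask IUPAC-ambiguous symbols, N and gaps as missing data,
# pairwise where the statistic is pairwise.

# 0/1/NA matrix helper: biallelic coding at one alignment column
.col_states <- function(col) {
  obs <- col[col %in% c("A", "C", "G", "T")]
  sort(unique(obs))
}

#' Extract segregating sites
#'
#' Scans an alignment for variable sites.  Biallelic sites are coded 0/1
#' (0 = alphabetically first observed state); sites with more than two
#' observed states are recorded in `multiallelic_positions` and excluded from
#' the binary matrix (and hence from LD statistics), but still count towards
#' `S` under the Watterson definition.
#'
#' @param x an [aln()] (DNA).
#' @return object of class `segsites`: list with `positions` (1-based site
#'   indices of biallelic sites, strictly increasing), `states` (n x S 0/1/NA
#'   matrix), `n`, `S` (all variable sites, incl. multiallelic),
#'   `multiallelic_positions`, `L` (alignment length).
#' @export
segregating_sites <- function(x) {
  m <- unclass(x)
  n <- nrow(m)
  if (n < 2L) stop("input-error: need at least 2 sequences")
  pos <- integer(0); multi <- integer(0)
  cols <- list()
  for (j in seq_len(ncol(m))) {
    st <- .col_states(m[, j])
    if (length(st) == 2L) {
      pos <- c(pos, j)
      v <- match(m[, j], st) - 1L          # 0/1, NA for missing/other
      v[!(m[, j] %in% st)] <- NA_integer_
      cols[[length(cols) + 1L]] <- v
    } else if (length(st) > 2L) {
      multi <- c(multi, j)
    }
  }
  states <- if (length(cols)) do.call(cbind, cols) else
    matrix(integer(0), nrow = n, ncol = 0)
  rownames(states) <- rownames(m)
  structure(list(positions = pos, states = states, n = n,
                 S = length(pos) + length(multi),
                 multiallelic_positions = multi, L = ncol(m)),
            class = "segsites")
}

#' @export
print.segsites <- function(x, ...) {
  cat(sprintf("segsites: n=%d, S=%d (%d biallelic, %d multiallelic), L=%d\n",
              x$n, x$S, length(x$positions),
              length(x$multiallelic_positions), x$L))
  invisible(x)
}

# pairwise difference counts over mutually non-missing sites
.pairwise_diffs <- function(m) {
  good <- matrix(m %in% c("A", "C", "G", "T"), nrow(m))
  n <- nrow(m)
  k <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- good[i, ] & good[j, ]
    k[i, j] <- k[j, i] <- sum(m[i, ok] != m[j, ok])
  }
  k
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences over all n(n-1)/2 sequence pairs,
#' counting only mutually non-missing sites for each pair.
#'
#' @param x an [aln()].
#' @return list with `per_gene` and `per_site` (per gene / alignment length).
#' @export
nucleotide_diversity <- function(x) {
  m <- unclass(x)
  if (nrow(m) < 2L) stop("input-error: need at least 2 sequences")
  k <- .pairwise_diffs(m)
  pg <- mean(k[upper.tri(k)])
  list(per_gene = pg, per_site = pg / ncol(m))
}

#' Watterson's theta
#'
#' `S / a1` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param ss a [segregating_sites()] object.
#' @return Watterson estimator (per gene).
#' @export
watterson_theta <- function(ss) {
  stopifnot(inherits(ss, "segsites"))
  a1 <- sum(1 / seq_len(ss$n - 1L))
  ss$S / a1
}

#' Tajima's D
#'
#' Normalized difference between pi and Watterson's theta with the standard
#' Tajima (1989) constants.  Undefined (returns `NA`) when S = 0.
#'
#' @param x an [aln()].
#' @return list with `D`, `pi`, `theta_w`, `S`, `n`.
#' @export
tajimas_d <- function(x) {
  ss <- segregating_sites(x)
  n <- ss$n; S <- ss$S
  if (n < 4L) stop("input-error: Tajima's D requires n >= 4")
  pi <- nucleotide_diversity(x)$per_gene
  a1 <- sum(1 / seq_len(n - 1L))
  if (S == 0L)
    return(list(D = NA_real_, pi = pi, theta_w = 0, S = 0L, n = n))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, pi = pi, theta_w = S / a1, S = S, n = n)
}

# two-locus coalescent decay of the squared-coefficient term:
# phi(C) = (2/C^2) * int_0^C (C-u) * (u+18)/(u^2+13u+18) du; phi(0) = 1.
# (u+18)/(u^2+13u+18) is the correlation of pairwise coalescence times for
# two loci at recombination distance u.
.phi_decay <- function(C) {
  if (C < 1e-8) return(1)
  f <- function(u) (C - u) * (u + 18) / (u^2 + 13 * u + 18)
  (2 / C^2) * integrate(f, 0, C, rel.tol = 1e-10)$value
}

#' Hudson's (1987) recombination estimator R
#'
#' Method-of-moments estimator of the per-gene population recombination rate
#' C = 4Nc from the variance of pairwise difference counts: the observed
#' variance S_k^2 is equated to its coalescent expectation
#' \deqn{E[S_k^2](C) = \frac{2n-4}{3(n-1)}\hat\pi +
#'   \left(1 - \frac{2(n^2+n+3)}{9n(n-1)}\right)\hat\pi^2\,\phi(C)}
#' where \eqn{\phi(C)} integrates the two-locus correlation of pair
#' coalescence times \eqn{(c+18)/(c^2+13c+18)} over site pairs, and the
#' C = 0 limit matches Tajima's no-recombination variance of pairwise
#' differences.  Larger excess variance implies smaller inferred R.  The root
#' is searched on C in [1e-6, 1e4] (bisection tolerance 1e-8).
#'
#' @param x an [aln()].
#' @param L_divisor divisor converting per-gene R to the per-adjacent-site
#'   rate; defaults to the number of analyzed sites (alignment length).
#' @return list with `R_gene`, `R_adjacent`, `S_k_sq` (observed variance),
#'   `pi`, `at_bound` flag.
#' @export
hudson_R <- function(x, L_divisor = NULL) {
  m <- unclass(x)
  n <- nrow(m)
  if (n < 2L) stop("input-error: need at least 2 sequences")
  ss <- segregating_sites(x)
  L <- if (is.null(L_divisor)) ss$L else L_divisor
  if (ss$S < 2L)
    return(list(R_gene = NA_real_, R_adjacent = NA_real_, S_k_sq = NA_real_,
                pi = NA_real_, at_bound = FALSE))
  k <- .pairwise_diffs(m)
  kk <- k[upper.tri(k)]
  pi <- mean(kk)
  sk2 <- mean((kk - pi)^2)          # population-style variance over pairs
  ct <- (2 * n - 4) / (3 * (n - 1)) * pi          # linear (mutational) term
  cq <- (1 - 2 * (n^2 + n + 3) / (9 * n * (n - 1))) * pi^2
  lo <- 1e-6; hi <- 1e4
  expected <- function(C) ct + cq * .phi_decay(C)
  at_bound <- FALSE
  if (cq <= 0 || sk2 >= expected(lo)) {
    # excess variance at/above the no-recombination expectation
    C <- lo; at_bound <- TRUE
  } else if (sk2 <= expected(hi)) {
    # variance below even the free-recombination expectation
    C <- hi; at_bound <- TRUE
  } else {
    C <- uniroot(function(C) expected(C) - sk2, c(lo, hi), tol = 1e-8)$root
  }
  list(R_gene = C, R_adjacent = C / L, S_k_sq = sk2, pi = pi,
       at_bound = at_bound)
}

# all-four-gametes incompatibility between two 0/1 columns (pairwise deletion)
.four_gametes <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(FALSE)
  g <- unique(a[ok] * 2L + b[ok])
  length(g) == 4L
}

#' Hudson-Kaplan minimum number of recombination events (Rm)
#'
#' Four-gamete test: every pair of biallelic sites showing all four gametes
#' among mutually non-missing rows defines an incompatible interval; Rm is the
#' maximum number of pairwise non-overlapping such (open) intervals, which
#' lower-bounds the number of historical recombination events.
#'
#' @param ss a [segregating_sites()] object.
#' @return integer Rm.
#' @export
four_gamete_Rm <- function(ss) {
  stopifnot(inherits(ss, "segsites"))
  S <- length(ss$positions)
  if (S <= 1L) return(0L)
  st <- ss$states
  iv <- list()
  for (i in seq_len(S - 1L)) for (j in (i + 1L):S) {
    if (.four_gametes(st[, i], st[, j]))
      iv[[length(iv) + 1L]] <- c(ss$positions[i], ss$positions[j])
  }
  if (!length(iv)) return(0L)
  ivm <- do.call(rbind, iv)
  # greedy interval scheduling on open intervals: sort by right endpoint;
  # intervals (a,b), (c,d) are disjoint iff b <= c
  o <- order(ivm[, 2L], ivm[, 1L])
  ivm <- ivm[o, , drop = FALSE]
  rm_count <- 0L; last_right <- -Inf
  for (r in seq_len(nrow(ivm))) {
    if (ivm[r, 1L] >= last_right) {
      rm_count <- rm_count + 1L
      last_right <- ivm[r, 2L]
    }
  }
  rm_count
}

# r^2 between two 0/1 columns with pairwise deletion; NA if monomorphic
.r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) return(NA_real_)
  va <- var(a); vb <- var(b)
  if (va == 0 || vb == 0) return(NA_real_)
  (cov(a, b) / sqrt(va * vb))^2
}

#' Za, ZnS and the ZZ recombination statistic
#'
#' `ZnS` is the mean r^2 over all pairs of biallelic segregating sites, `Za`
#' the mean r^2 over the S-1 physically adjacent pairs (in position order),
#' and `ZZ = Za - ZnS`.  Elevated ZZ indicates intragenic recombination.
#'
#' @param ss a [segregating_sites()] object.
#' @return list with `Za`, `ZnS`, `ZZ` (all `NA` when fewer than two biallelic
#'   sites).
#' @export
zz_statistic <- function(ss) {
  stopifnot(inherits(ss, "segsites"))
  S <- length(ss$positions)
  if (S < 2L)
    return(list(Za = NA_real_, ZnS = NA_real_, ZZ = NA_real_))
  st <- ss$states
  if (!anyNA(st)) {                      # complete data: one cor() call
    r2m <- suppressWarnings(cor(st))^2
    up <- upper.tri(r2m)
    ZnS <- mean(r2m[up], na.rm = TRUE)
    Za <- mean(r2m[cbind(seq_len(S - 1L), 2L:S)], na.rm = TRUE)
  } else {
    r2all <- c(); r2adj <- c()
    for (i in seq_len(S - 1L)) for (j in (i + 1L):S) {
      r2 <- .r2(st[, i], st[, j])
      r2all <- c(r2all, r2)
      if (j == i + 1L) r2adj <- c(r2adj, r2)
    }
    Za <- mean(r2adj, na.rm = TRUE)
    ZnS <- mean(r2all, na.rm = TRUE)
  }
  list(Za = Za, ZnS = ZnS, ZZ = Za - ZnS)
}

#' Tajima's D directly from segregating sites
#'
#' Fast path for simulated (missing-free, biallelic) `segsites`: pi is
#' computed from derived-allele counts per site, theta from `S`.
#'
#' @param ss a `segsites` object with complete 0/1 states.
#' @return Tajima's D (NA when S = 0).
#' @export
tajimas_d_segsites <- function(ss) {
  stopifnot(inherits(ss, "segsites"), !anyNA(ss$states))
  n <- ss$n; S <- ss$S
  if (n < 4L) stop("input-error: Tajima's D requires n >= 4")
  if (S == 0L) return(NA_real_)
  d1 <- colSums(ss$states)
  pi <- sum(d1 * (n - d1)) / (n * (n - 1) / 2)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' One-row popgen summary of an alignment
#'
#' Convenience wrapper computing every observed column of a
#' recombination/neutrality table: pi, Watterson's theta, Tajima's D,
#' Hudson's R (per gene and per adjacent site), Rm, and Za/ZnS/ZZ.
#'
#' @param x an [aln()].
#' @return a one-row `data.frame`.
#' @export
popgen_summary <- function(x) {
  ss <- segregating_sites(x)
  pi <- nucleotide_diversity(x)
  td <- if (ss$n >= 4L) tajimas_d(x)$D else NA_real_
  hr <- hudson_R(x)
  zz <- zz_statistic(ss)
  data.frame(n = ss$n, L = ss$L, S = ss$S,
             pi_gene = pi$per_gene, pi_site = pi$per_site,
             theta_w = watterson_theta(ss), tajima_d = td,
             R_gene = hr$R_gene, R_adjacent = hr$R_adjacent,
             Rm = four_gamete_Rm(ss),
             Za = zz$Za, ZnS = zz$ZnS, ZZ = zz$ZZ)
}
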