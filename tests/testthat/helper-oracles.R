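# Independent brute-force oracles and small fixture generators.  These
# deliberately re-derive every quantity with the most naive algorithm
# available so they share no code path with the package implementations.

rand_aln <- function(n, L, alphabet = c("A", "C", "G", "T"), miss = 0) {
  m <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  if (miss > 0) m[sample(length(m), round(miss * length(m)))] <- "N"
  rownames(m) <- paste0("s", seq_len(n))
  aln(m)
}

# pi by explicit double loop over pairs and sites
brute_pi <- function(x) {
  m <- unclass(x)
  n <- nrow(m)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- 0
    for (s in seq_len(ncol(m))) {
      a <- m[i, s]; b <- m[j, s]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T") &&
          a != b) d <- d + 1
    }
    tot <- tot + d; np <- np + 1
  }
  tot / np
}

# r^2 between two 0/1 vectors from first principles (2x2 table)
brute_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  pa <- mean(a); pb <- mean(b); pab <- mean(a & b)
  D <- pab - pa * pb
  den <- pa * (1 - pa) * pb * (1 - pb)
  if (den == 0) return(NA_real_)
  D^2 / den
}

brute_zz <- function(ss) {
  S <- length(ss$positions)
  allr <- c(); adjr <- c()
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    r <- brute_r2(ss$states[, i], ss$states[, j])
    allr <- c(allr, r)
    if (j == i + 1) adjr <- c(adjr, r)
  }
  list(Za = mean(adjr, na.rm = TRUE), ZnS = mean(allr, na.rm = TRUE))
}

# exhaustive max set of pairwise-disjoint incompatible open intervals
brute_rm <- function(ss) {
  S <- length(ss$positions)
  if (S <= 1) return(0L)
  iv <- list()
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    a <- ss$states[, i]; b <- ss$states[, j]
    ok <- !is.na(a) & !is.na(b)
    if (length(unique(paste(a[ok], b[ok]))) == 4)
      iv[[length(iv) + 1]] <- c(ss$positions[i], ss$positions[j])
  }
  k <- length(iv)
  if (k == 0) return(0L)
  bestv <- 0L
  for (mask in seq_len(2^k) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) != 0)
    if (length(sel) <= bestv) next
    ivs <- iv[sel]
    ok <- TRUE
    if (length(ivs) > 1) {
      for (p in seq_len(length(ivs) - 1)) for (q in (p + 1):length(ivs)) {
        lo <- ivs[[p]]; hi <- ivs[[q]]
        if (lo[1] > hi[1]) { t <- lo; lo <- hi; hi <- t }
        if (hi[1] < lo[2]) { ok <- FALSE; break }   # open intervals overlap
      }
    }
    if (ok) bestv <- length(ivs)
  }
  bestv
}

# independent NG86 oracle: recursive pathway enumeration with explicit
# per-step classification (no shared code with the package)
ng86_oracle <- function(codons_a, codons_b) {
  GC <- Biostrings::GENETIC_CODE
  nt <- c("A", "C", "G", "T")
  syn_sites <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) {
      hits <- 0; den <- 0
      for (b in nt[nt != ch[p]]) {
        mut <- ch; mut[p] <- b
        mc <- paste(mut, collapse = "")
        if (GC[[mc]] == "*") next
        den <- den + 1
        if (GC[[mc]] == GC[[cod]]) hits <- hits + 1
      }
      if (den > 0) s <- s + hits / den
    }
    s
  }
  count_paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(c(0, 0, 1))
    acc <- c(0, 0, 0)    # syn, nonsyn, n_paths
    for (p in pos) {
      ch <- strsplit(from, "")[[1]]
      ch[p] <- strsplit(to, "")[[1]][p]
      mid <- paste(ch, collapse = "")
      if (GC[[mid]] == "*") next
      sub <- count_paths(mid, to)
      if (sub[3] == 0) next
      step_syn <- as.numeric(GC[[from]] == GC[[mid]])
      acc <- acc + c(sub[1] + step_syn * sub[3],
                     sub[2] + (1 - step_syn) * sub[3], sub[3])
    }
    acc
  }
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(codons_a)) {
    ca <- codons_a[k]; cb <- codons_b[k]
    s <- (syn_sites(ca) + syn_sites(cb)) / 2
    S <- S + s; N <- N + 3 - s
    cp <- count_paths(ca, cb)
    if (cp[3] > 0) {
      Sd <- Sd + cp[1] / cp[3]; Nd <- Nd + cp[2] / cp[3]
    } else {
      Nd <- Nd + length(which(strsplit(ca, "")[[1]] !=
                                strsplit(cb, "")[[1]]))
    }
  }
  list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd)
}

rand_sense_codons <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  sample(sense, n, replace = TRUE)
}

# small codon alignment + tree fixture used across codon-model tests
codon_fixture <- function(seed = 101, n_codons = 150, omega = 0.3) {
  tr <- simulate_tree("yule", 5, birth = 1, seed = seed)
  tr$edge.length <- tr$edge.length * 0.3
  sim <- simulate_codon_alignment(tr, n_codons, kappa = 2, omega = omega,
                                  seed = seed + 1)
  list(tree = tr, sim = sim, ca = sim$ca)
}
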