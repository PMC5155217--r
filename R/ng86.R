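# Nei-Gojobori (1986) synonymous/nonsynonymous counting with pathway
# averaging (proportion method; no multiple-hit correction).

# synonymous site fraction of one codon: for each position, the fraction of
# the 3 single-nucleotide neighbours that are synonymous (stop neighbours
# excluded from the denominator)
.syn_sites_codon <- function(codon, cs) {
  nt <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  aa0 <- cs$code$aa[codon]
  s <- 0
  for (p in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(nt, chars[p])) {
      mut <- chars; mut[p] <- b
      mc <- paste(mut, collapse = "")
      if (cs$code$aa[mc] == "*") next
      valid <- valid + 1
      if (cs$code$aa[mc] == aa0) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

# average syn/nonsyn difference counts between two codons over all minimal
# mutational pathways (stop-passing pathways excluded)
.path_diffs <- function(c1, c2, cs) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  if (is.null(.codon_env$pathcache))
    .codon_env$pathcache <- new.env(parent = emptyenv())
  key <- paste0(c1, c2)
  hit <- .codon_env$pathcache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- if (length(pos) == 1L) list(pos) else {
    pl <- list()
    permute <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in permute(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      out
    }
    permute(pos)
  }
  tot_sd <- 0; tot_nd <- 0; nvalid <- 0
  target <- strsplit(c2, "")[[1]]
  for (ord in perms) {
    cur <- strsplit(c1, "")[[1]]
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- target[p]
      nxt <- paste(cur, collapse = "")
      if (cs$code$aa[nxt] == "*") { ok <- FALSE; break }
      if (cs$code$aa[prev] == cs$code$aa[nxt]) sd <- sd + 1 else nd <- nd + 1
    }
    if (ok) { tot_sd <- tot_sd + sd; tot_nd <- tot_nd + nd; nvalid <- nvalid + 1 }
  }
  res <- if (nvalid == 0L) {
    # all pathways pass a stop: fall back to counting every change nonsyn
    c(sd = 0, nd = length(pos))
  } else c(sd = tot_sd / nvalid, nd = tot_nd / nvalid)
  .codon_env$pathcache[[key]] <- res
  res
}

#' Nei-Gojobori substitution counts between two codon sequences
#'
#' Synonymous site fractions are computed per codon by enumerating the three
#' single-nucleotide neighbours at each position; multi-step codon
#' differences are averaged over all minimal mutational pathways that avoid
#' stop codons.  `pS = Sd/S_sites`, `pN = Nd/N_sites` (proportion method, no
#' correction); `dN`, `dS` carry the Jukes-Cantor correction and `omega =
#' dN/dS` (flagged infinite when `dS = 0`, reported as `Inf`).
#' Gapped/ambiguous codons and codons absent from the sense set are masked
#' pairwise.
#'
#' @param seq_a,seq_b codon sequences: character strings, vectors of codons,
#'   or rows of a codon alignment (see [to_codon_alignment()]).
#' @param code a [genetic_code()].
#' @return list with `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`,
#'   `dN`, `omega`, `omega_infinite`, `n_codons_compared`.
#' @export
ng86_counts <- function(seq_a, seq_b, code = genetic_code()) {
  cs <- codon_setup(code)
  tocod <- function(s) {
    if (length(s) == 1L && nchar(s) > 3L)
      s <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    toupper(s)
  }
  a <- tocod(seq_a); b <- tocod(seq_b)
  if (length(a) != length(b))
    stop("input-error: unequal codon counts")
  ok <- a %in% cs$sense & b %in% cs$sense
  a <- a[ok]; b <- b[ok]
  if (!length(a))
    return(list(S_sites = NA_real_, N_sites = NA_real_, Sd = NA_real_,
                Nd = NA_real_, pS = NA_real_, pN = NA_real_, dS = NA_real_,
                dN = NA_real_, omega = NA_real_, omega_infinite = NA,
                n_codons_compared = 0L))
  syn_cache <- .codon_env[[paste0(code$id, "_synsites")]]
  if (is.null(syn_cache)) {
    syn_cache <- vapply(cs$sense, .syn_sites_codon, 0, cs = cs)
    .codon_env[[paste0(code$id, "_synsites")]] <- syn_cache
  }
  Ssites <- sum((syn_cache[a] + syn_cache[b]) / 2)
  Nsites <- 3 * length(a) - Ssites
  d <- mapply(function(x, y) .path_diffs(x, y, cs), a, b)
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- Sd / Ssites; pN <- Nd / Nsites
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -3 / 4 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  inf <- !is.na(dS) && dS == 0 && !is.na(dN) && dN > 0
  omega <- if (is.na(dS) || is.na(dN)) NA_real_ else
    if (dS == 0) { if (dN == 0) NA_real_ else Inf } else dN / dS
  list(S_sites = Ssites, N_sites = Nsites, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN, dS = dS, dN = dN,
       omega = omega, omega_infinite = inf,
       n_codons_compared = length(a))
}
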