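# Codon-usage indices: Wright's effective number of codons (ENC), the codon
# bias index (CBI), GC content at third positions, the ENC-GC3 neutral
# expectation curve, and group comparison by t-test.

# synonymous families of the standard code, excluding Met, Trp and stops
.codon_families <- function(code = genetic_code()) {
  key <- paste0(code$id, "_families")
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  aa <- code$aa[code$sense]
  fam <- split(code$sense, aa)
  fam <- fam[vapply(fam, length, 0L) >= 2L]    # degenerate families only
  .codon_env[[key]] <- fam
  fam
}

.as_codons <- function(x, code) {
  if (inherits(x, "codon_aln")) stop("pass one sequence, not an alignment")
  if (length(x) == 1L && nchar(x) > 3L)
    x <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  x <- toupper(x)
  x[x %in% code$sense]
}

#' Effective number of codons (ENC)
#'
#' Wright (1990): for each degenerate amino-acid family with n observed
#' codons and usage proportions p_i, the homozygosity is
#' `F = (n sum p_i^2 - 1)/(n - 1)`; family means F_k are averaged within each
#' degeneracy class k and `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` (standard
#' code family counts).  Families with fewer than 2 observations are
#' skipped; a missing F3 class is imputed as the mean of F2 and F4; ENC is
#' clamped at 61.  ENC = 20 means one codon per amino acid (maximal bias),
#' 61 means no bias.
#'
#' @param x a codon sequence (string or codon vector).
#' @param code a [genetic_code()].
#' @return ENC value in [20, 61] (`NA` if no multi-codon family is observed).
#' @export
enc <- function(x, code = genetic_code()) {
  cods <- .as_codons(x, code)
  fams <- .codon_families(code)
  deg <- vapply(fams, length, 0L)
  Fhat <- rep(NA_real_, length(fams))
  for (i in seq_along(fams)) {
    obs <- cods[cods %in% fams[[i]]]
    n <- length(obs)
    if (n < 2L) next
    p <- as.numeric(table(factor(obs, levels = fams[[i]]))) / n
    Fhat[i] <- (n * sum(p^2) - 1) / (n - 1)
  }
  Fbar <- vapply(c(2L, 3L, 4L, 6L), function(k) {
    v <- Fhat[deg == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  names(Fbar) <- c("F2", "F3", "F4", "F6")
  if (is.na(Fbar["F3"]) && !is.na(Fbar["F2"]) && !is.na(Fbar["F4"]))
    Fbar["F3"] <- mean(c(Fbar["F2"], Fbar["F4"]))
  if (anyNA(Fbar)) return(NA_real_)
  Fbar <- pmax(Fbar, 1e-6)
  val <- 2 + 9 / Fbar["F2"] + 1 / Fbar["F3"] + 5 / Fbar["F4"] + 3 / Fbar["F6"]
  unname(min(val, 61))
}

#' Wright's ENC-GC3 neutral expectation
#'
#' `ENC*(s) = 2 + s + 29/(s^2 + (1-s)^2)` with s = GC3; the expected ENC in
#' the absence of selection at a given third-position GC content.  Boundary
#' values are returned by limit at s in \{0, 1\}.
#'
#' @param gc3 third-position GC content(s) in [0, 1].
#' @return expected ENC value(s).
#' @export
enc_expected <- function(gc3) {
  stopifnot(all(gc3 >= 0), all(gc3 <= 1))
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' GC content at codon third positions
#' @param x codon sequence (string or codon vector).
#' @param code a [genetic_code()].
#' @return GC3 in [0, 1].
#' @export
gc3 <- function(x, code = genetic_code()) {
  cods <- .as_codons(x, code)
  third <- substring(cods, 3, 3)
  mean(third %in% c("G", "C"))
}

#' Codon bias index (CBI)
#'
#' `CBI = (N_opt - N_ran) / (N_tot - N_ran)` where `N_opt` counts optimal
#' codons, `N_tot` all codons of degenerate amino acids, and `N_ran` the
#' expected optimal count under uniform synonymous usage.  CBI = 1 when all
#' codons are optimal; 0 under uniform usage.
#'
#' @param x codon sequence.
#' @param optimal_codons character vector with exactly one sense codon per
#'   degenerate amino acid; see [infer_optimal_codons()].
#' @param code a [genetic_code()].
#' @return CBI in [-1, 1] (`NA` when the denominator degenerates).
#' @export
cbi <- function(x, optimal_codons, code = genetic_code()) {
  cods <- .as_codons(x, code)
  fams <- .codon_families(code)
  aa_opt <- code$aa[optimal_codons]
  if (anyDuplicated(aa_opt))
    stop("input-error: more than one optimal codon for an amino acid")
  n_opt <- 0; n_tot <- 0; n_ran <- 0
  for (i in seq_along(fams)) {
    fam <- fams[[i]]
    obs <- cods[cods %in% fam]
    if (!length(obs)) next
    opt <- intersect(optimal_codons, fam)
    if (!length(opt)) next
    n_tot <- n_tot + length(obs)
    n_opt <- n_opt + sum(obs %in% opt)
    n_ran <- n_ran + length(obs) / length(fam)
  }
  if (n_tot == n_ran) return(NA_real_)
  (n_opt - n_ran) / (n_tot - n_ran)
}

#' Infer an optimal-codon set as the modal codon per amino acid
#'
#' Pools all sequences of a codon alignment and picks, for each degenerate
#' amino acid, its most frequent codon (ties broken alphabetically, so the
#' rule is reproducible).
#'
#' @param ca a codon alignment (or character vector of codon sequences).
#' @param code a [genetic_code()].
#' @return character vector of optimal codons.
#' @export
infer_optimal_codons <- function(ca, code = genetic_code()) {
  cods <- if (inherits(ca, "codon_aln")) {
    cc <- codon_strings(ca); cc[!is.na(cc)]
  } else unlist(lapply(ca, .as_codons, code = code))
  fams <- .codon_families(code)
  vapply(fams, function(fam) {
    cnt <- table(factor(cods[cods %in% fam], levels = sort(fam)))
    names(cnt)[which.max(cnt)]    # which.max takes the first (alphabetical) tie
  }, "")
}

#' Per-sequence codon-usage table and group comparison
#'
#' @param ca a codon alignment.
#' @param groups named character/factor: group label per sequence id; when
#'   NULL all sequences form one group.
#' @param optimal_codons optional fixed optimal set; inferred from the
#'   pooled alignment when NULL.
#' @param code a [genetic_code()].
#' @return `codon_usage` list: `table` (per-sequence ENC/CBI/GC3/ENC
#'   expectation), `group_summary`, `tests` (Welch t for ENC and CBI when 2
#'   groups), `optimal_codons`.
#' @export
codon_usage <- function(ca, groups = NULL, optimal_codons = NULL,
                        code = genetic_code()) {
  stopifnot(inherits(ca, "codon_aln"))
  cods <- codon_strings(ca)
  ids <- rownames(cods)
  if (is.null(optimal_codons)) optimal_codons <- infer_optimal_codons(ca, code)
  tab <- data.frame(
    id = ids,
    ENC = vapply(ids, function(i) enc(na.omit(cods[i, ]), code), 0),
    CBI = vapply(ids, function(i) cbi(na.omit(cods[i, ]), optimal_codons,
                                      code), 0),
    GC3 = vapply(ids, function(i) gc3(na.omit(cods[i, ]), code), 0),
    row.names = NULL)
  tab$ENC_expected <- enc_expected(tab$GC3)
  grp <- if (is.null(groups)) setNames(rep("all", length(ids)), ids) else groups
  tab$group <- as.character(grp[tab$id])
  gs <- do.call(rbind, lapply(split(tab, tab$group), function(d)
    data.frame(group = d$group[1], n = nrow(d),
               ENC_mean = mean(d$ENC), ENC_sd = sd(d$ENC),
               CBI_mean = mean(d$CBI), CBI_sd = sd(d$CBI),
               row.names = NULL)))
  tests <- NULL
  if (length(unique(tab$group)) == 2L) {
    sp <- split(tab, tab$group)
    tests <- list(ENC = compare_groups(sp[[1]]$ENC, sp[[2]]$ENC),
                  CBI = compare_groups(sp[[1]]$CBI, sp[[2]]$CBI))
  }
  structure(list(table = tab, group_summary = gs, tests = tests,
                 optimal_codons = optimal_codons), class = "codon_usage")
}

#' Two-group comparison of an index
#'
#' Welch two-sample t-test by default (classical equal-variance Student test
#' behind `equal_var = TRUE`); reports group means with SDs and the
#' two-sided p.  When both groups have zero variance and equal means,
#' `t = 0, p = 1` by convention.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param equal_var use the pooled-variance Student variant.
#' @return list with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`, `df`, `p`.
#' @export
compare_groups <- function(a, b, equal_var = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (sd(a) == 0 && sd(b) == 0) {
    return(list(mean_a = mean(a), sd_a = 0, mean_b = mean(b), sd_b = 0,
                t = if (mean(a) == mean(b)) 0 else Inf,
                df = length(a) + length(b) - 2L,
                p = if (mean(a) == mean(b)) 1 else 0))
  }
  tt <- t.test(a, b, var.equal = equal_var)
  list(mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
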