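#' @importFrom stats optim optimize uniroot runif rexp rbinom rpois rgamma
#'   var cov cor sd t.test pchisq pnorm qbeta quantile setNames integrate
#'   na.omit rnorm dist plogis qlogis reorder
#' @importFrom utils head tail write.table
NULL

# symbols treated as missing data by all statistics (IUPAC ambiguity + gap + N)
.MISSING_NT <- setdiff(c(LETTERS, "-", "?", "."), c("A", "C", "G", "T"))

#' Aligned sequence matrix
#'
#' An `aln` object is a character matrix (rows = sequences, columns = sites)
#' with unique rownames, all symbols upper-case.  It is the substrate of every
#' statistic in the package.
#'
#' @param seqs character vector of equal-length sequence strings, or a
#'   character matrix of single symbols.
#' @param ids unique sequence identifiers (defaults to names of `seqs`).
#' @param type `"dna"` or `"protein"`; stored as an attribute only.
#' @return an object of class `aln`.
#' @export
aln <- function(seqs, ids = names(seqs), type = "dna") {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
    if (!is.null(ids)) rownames(m) <- ids
  } else {
    force(ids)                      # capture names before they are dropped
    seqs <- toupper(as.character(seqs))
    if (length(seqs) == 0L) stop("format-error: no sequences")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment-error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                nrow = length(seqs), byrow = TRUE)
    rownames(m) <- if (is.null(ids)) paste0("seq", seq_along(seqs)) else ids
  }
  if (ncol(m) < 1L) stop("alignment-error: zero-length alignment")
  if (anyDuplicated(rownames(m)))
    stop("format-error: duplicate sequence ids")
  structure(m, class = "aln", type = type)
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("aln: %d sequences x %d sites (%s)\n",
              nrow(x), ncol(x), attr(x, "type") %||% "dna"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a FASTA alignment
#'
#' Reads a FASTA file, validates that all records have equal length and unique
#' ids, and returns an [aln()] with upper-cased symbols ('-' preserved).
#'
#' @param path path to a FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return an [aln()] object.
#' @export
read_fasta <- function(path, type = "dna") {
  if (!file.exists(path)) stop("format-error: file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("format-error: empty FASTA file")
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("format-error: duplicate ids in ", path)
  aln(as.character(ss), ids = ids, type = type)
}

#' Write a FASTA alignment
#' @param x an [aln()] or codon alignment.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "codon_aln")) x <- x$aln
  seqs <- apply(unclass(x), 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Genetic code table
#'
#' Wraps a codon-to-amino-acid map (64 codons; the standard code has 61 sense
#' codons and 3 stops, '*').
#'
#' @param id genetic code identifier; only `"standard"` ships with the package.
#' @return list with `codons`, `aa` (named map codon -> single-letter amino
#'   acid, '*' for stop), `stops`, and `sense` (the ordered sense codons).
#' @export
genetic_code <- function(id = "standard") {
  if (id != "standard") stop("unknown genetic code: ", id)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- as.character(gc)
  names(aa) <- codons
  stopifnot(length(aa) == 64L)
  list(id = id, aa = aa, codons = codons,
       stops = codons[aa == "*"], sense = codons[aa != "*"])
}

#' Convert an alignment to a frame-checked codon alignment
#'
#' Length must be divisible by 3.  A shared terminal stop codon column block is
#' stripped (standard codeml convention).  Sequences with internal stop codons
#' are rejected unless `allow_stops = TRUE`, in which case they are flagged as
#' pseudogenes: they stay in the alignment for reporting but are meant to be
#' excluded from codon-model fitting.
#'
#' @param x an [aln()].
#' @param code a [genetic_code()].
#' @param allow_stops keep sequences with internal stops, flagging them.
#' @return object of class `codon_aln`: list with `aln`, `n_codons`, `code_id`,
#'   `pseudogene` (logical per sequence).
#' @export
to_codon_alignment <- function(x, code = genetic_code(), allow_stops = FALSE) {
  stopifnot(inherits(x, "aln"))
  L <- ncol(x)
  if (L %% 3L != 0L)
    stop("frame-error: alignment length ", L, " not divisible by 3")
  cods <- codon_strings(x)
  nc <- ncol(cods)
  # strip terminal stop codons (any sequence ending in a stop)
  last <- cods[, nc]
  if (any(last %in% code$stops)) {
    x <- aln(unclass(x)[, seq_len(L - 3L), drop = FALSE],
             ids = rownames(x), type = "dna")
    cods <- cods[, -nc, drop = FALSE]
    nc <- nc - 1L
  }
  aa <- matrix(code$aa[cods], nrow = nrow(cods))
  internal_stop <- apply(aa == "*" & !is.na(aa), 1L, any)
  if (any(internal_stop) && !allow_stops)
    stop("stop-error: internal stop codon in ",
         paste(rownames(x)[internal_stop], collapse = ", "),
         " (use allow_stops = TRUE to flag as pseudogene)")
  structure(list(aln = x, n_codons = nc, code_id = code$id,
                 pseudogene = setNames(internal_stop, rownames(x))),
            class = "codon_aln")
}

#' @export
print.codon_aln <- function(x, ...) {
  cat(sprintf("codon alignment: %d sequences x %d codons (%d pseudogene)\n",
              nrow(x$aln), x$n_codons, sum(x$pseudogene)))
  invisible(x)
}

# rows x codons matrix of 3-letter codon strings; codons containing any
# non-ACGT symbol are returned as NA (masked)
codon_strings <- function(x) {
  m <- unclass(if (inherits(x, "codon_aln")) x$aln else x)
  L <- ncol(m)
  stopifnot(L %% 3L == 0L)
  nc <- L %/% 3L
  out <- matrix(NA_character_, nrow(m), nc, dimnames = list(rownames(m), NULL))
  for (k in seq_len(nc)) {
    sub <- m[, (3L * k - 2L):(3L * k), drop = FALSE]
    cod <- paste0(sub[, 1L], sub[, 2L], sub[, 3L])
    ok <- rowSums(matrix(!(sub %in% c("A", "C", "G", "T")), nrow(m))) == 0L
    out[ok, k] <- cod[ok]
  }
  out
}

#' Read / write Newick trees
#'
#' Thin validated wrappers around ape's Newick parser.  Round-trips preserve
#' topology and branch lengths to 1e-9.
#'
#' @param path file path (or a Newick string for `read_newick(text=)`).
#' @param text optional literal Newick string.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("parse-error: invalid Newick input")
  if (anyDuplicated(tr$tip.label)) stop("validation-error: duplicate tip labels")
  if (!is.null(tr$edge.length)) {
    if (any(!is.finite(tr$edge.length)))
      stop("validation-error: non-finite branch length")
    if (any(tr$edge.length < 0))
      stop("validation-error: negative branch length")
  }
  tr
}

#' @rdname read_newick
#' @param tree an `ape::phylo` object.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 12)
  if (!is.null(path)) { writeLines(s, path); invisible(path) } else s
}

#' Validate an alignment file
#'
#' Convenience check used by the command-line entry point: parses the file and
#' reports dimensions and (for in-frame data) codon diagnostics.
#'
#' @param path FASTA path.
#' @return invisibly, a list with `n`, `length`, `in_frame`, `pseudogene`.
#' @export
validate_alignment <- function(path) {
  a <- read_fasta(path)
  in_frame <- ncol(a) %% 3L == 0L
  pg <- logical(nrow(a))
  if (in_frame) {
    ca <- tryCatch(to_codon_alignment(a, allow_stops = TRUE),
                   error = function(e) NULL)
    if (!is.null(ca)) pg <- ca$pseudogene
  }
  res <- list(n = nrow(a), length = ncol(a), in_frame = in_frame,
              pseudogene = pg)
  message(sprintf("%s: %d sequences, %d sites, %s frame%s", path, res$n,
                  res$length, if (in_frame) "in" else "out of",
                  if (any(pg)) paste0("; pseudogene flags: ",
                                      paste(rownames(a)[pg], collapse = ",")) else ""))
  invisible(res)
}
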