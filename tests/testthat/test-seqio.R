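test_that("FASTA parsing validates, normalizes and round-trips", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt", ">b", "ACGA"), tf)
  a <- read_fasta(tf)
  expect_s3_class(a, "aln")
  expect_equal(nrow(a), 2L)
  expect_equal(ncol(a), 4L)
  expect_equal(unname(unclass(a)[1, ]), c("A", "C", "G", "T"))  # upper-cased

  tf2 <- tempfile(fileext = ".fasta")
  write_fasta(a, tf2)
  expect_equal(unclass(read_fasta(tf2)), unclass(a))

  # ragged lengths
  writeLines(c(">a", "ACGT", ">b", "ACGTA"), tf)
  expect_error(read_fasta(tf), "alignment-error")
  # duplicate ids
  writeLines(c(">a", "ACGT", ">a", "ACGA"), tf)
  expect_error(read_fasta(tf), "format-error")
  # empty file
  writeLines(character(0), tf)
  expect_error(read_fasta(tf), "format-error|no sequences|empty")
})

test_that("codon alignment enforces frame and flags pseudogenes", {
  # Met-Lys-Stop: terminal stop stripped, 2 codons remain
  a <- aln(c(x = "ATGAAATGA", y = "ATGAAATGA"))
  ca <- to_codon_alignment(a)
  expect_equal(ca$n_codons, 2L)
  expect_false(any(ca$pseudogene))

  # internal stop rejected unless allowed
  b <- aln(c(x = "ATGTGAAAA", y = "ATGAAAAAA"))
  expect_error(to_codon_alignment(b), "stop-error")
  cb <- to_codon_alignment(b, allow_stops = TRUE)
  expect_true(cb$pseudogene[["x"]])
  expect_false(cb$pseudogene[["y"]])

  # frame error
  expect_error(to_codon_alignment(aln(c(x = "ACGT", y = "ACGA"))),
               "frame-error")
  # codon count identity
  z <- aln(c(x = paste(rep("ACA", 7), collapse = "")))
  expect_equal(to_codon_alignment(z)$n_codons, 7L)
})

test_that("genetic code table has 61 sense codons and 3 stops", {
  gc <- genetic_code()
  expect_length(gc$aa, 64L)
  expect_length(gc$sense, 61L)
  expect_length(gc$stops, 3L)
  expect_setequal(gc$stops, c("TAA", "TAG", "TGA"))
})

test_that("Newick IO validates and round-trips branch lengths", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3L)
  s <- write_newick(tr)
  tr2 <- read_newick(text = s)
  expect_equal(tr2$tip.label, tr$tip.label)
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-9)

  expect_error(read_newick(text = "((A:1,B:1):1,C:2"), "parse-error")
  expect_error(read_newick(text = "((A:1,B:-1):1,C:2);"),
               "validation-error")
})
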