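Package: dupsel
Title: Selection, Recombination and Functional Divergence of Duplicated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for inferring the evolutionary fate of
    duplicated gene families from coding-sequence alignments: diversity,
    neutrality and recombination statistics (pi, Watterson's theta, Tajima's D,
    Hudson's R, the Hudson-Kaplan minimum recombination count Rm and the
    Za/ZnS/ZZ linkage-disequilibrium statistics) with coalescent null
    distributions; codon-substitution likelihood models (M0, free-ratio, M1a,
    M2a, M7, M8, M8a and branch-site model A) with likelihood-ratio tests,
    naive empirical Bayes site posteriors and RELL-based KH/SH topology tests;
    Nei-Gojobori substitution counting; Gu type-I and type-II functional
    divergence between duplicate clades with radical/conserved substitution
    classification; codon-usage indices (ENC, CBI) and the ENC-GC3 expectation
    curve; distance-based trees, lineage-through-time curves and the
    gamma-statistic of diversification; plus synthetic-data generators with
    known ground truth so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
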