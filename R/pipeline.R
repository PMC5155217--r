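# Staged, seeded, logged orchestration of the full duplicate-gene analysis:
# popgen + coalescent nulls -> trees/gamma -> codon-model selection ->
# codon usage -> functional divergence, with a consolidated report.

#' Pipeline run configuration
#'
#' @param codon_fasta path to the coding alignment (FASTA), or a codon
#'   alignment object.
#' @param full_fasta optional full-length (exon+intron) alignment path/object
#'   for the popgen stage.
#' @param tree optional `phylo` or Newick path; estimated by NJ on p-distance
#'   when absent.
#' @param clades list with `dup1`, `dup2` tip-label vectors, or the string
#'   `"suffix"` to split tips on the `_dup1`/`_dup2` naming rule, or
#'   `"bipartition"` to use the deepest bipartition separating two
#'   species-complete clades.
#' @param stages character subset of
#'   `c("popgen", "coalnull", "gamma", "selection", "codonusage",
#'   "divergence")`.
#' @param reps coalescent replicates for the null-distribution stage.
#' @param boot bootstrap replicates for divergence SEs.
#' @param seed integer seed (mandatory when any stochastic stage enabled).
#' @return a `run_config` list.
#' @export
run_config <- function(codon_fasta, full_fasta = NULL, tree = NULL,
                       clades = "suffix",
                       stages = c("popgen", "coalnull", "gamma", "selection",
                                  "codonusage", "divergence"),
                       reps = 1000L, boot = 200L, seed = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(seed) && any(c("coalnull", "divergence") %in% stages))
    stop("input-error: seed is mandatory when stochastic stages are enabled")
  structure(list(codon_fasta = codon_fasta, full_fasta = full_fasta,
                 tree = tree, clades = clades, stages = stages,
                 reps = as.integer(reps), boot = as.integer(boot),
                 seed = seed),
            class = "run_config")
}

#' Assign tips to the two duplicate clades
#'
#' @param tree rooted `phylo` tree.
#' @param rule `"suffix"` (names ending `_dup1`/`_dup2`), `"bipartition"`
#'   (deepest bipartition splitting two species-complete clades, species =
#'   label prefix before the last underscore), or a list with `dup1`,
#'   `dup2` tip vectors.
#' @return list with `dup1` and `dup2` tip-label vectors.
#' @export
clade_assign <- function(tree, rule = "suffix") {
  if (is.list(rule) && !is.null(rule$dup1)) {
    stopifnot(all(c(rule$dup1, rule$dup2) %in% tree$tip.label))
    return(list(dup1 = rule$dup1, dup2 = rule$dup2))
  }
  if (identical(rule, "suffix")) {
    d1 <- grep("_dup1$", tree$tip.label, value = TRUE)
    d2 <- grep("_dup2$", tree$tip.label, value = TRUE)
    if (!length(d1) || !length(d2))
      stop("assignment-error: no _dup1/_dup2 suffixes found")
    return(list(dup1 = d1, dup2 = d2))
  }
  if (identical(rule, "bipartition")) {
    if (!ape::is.rooted(tree))
      stop("assignment-error: unrooted tree; supply an outgroup or root it")
    sp_of <- function(x) sub("_[^_]*$", "", x)
    ntip <- length(tree$tip.label)
    allsp <- unique(sp_of(tree$tip.label))
    # candidate: each child clade of an internal node containing every
    # species exactly once; pick the deepest bipartition whose two sides
    # are both species-complete
    for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
      tips <- tree$tip.label[.tips_below(tree, nd)]
      rest <- setdiff(tree$tip.label, tips)
      if (setequal(sp_of(tips), allsp) && setequal(sp_of(rest), allsp) &&
          !anyDuplicated(sp_of(tips)) && !anyDuplicated(sp_of(rest)))
        return(list(dup1 = sort(tips), dup2 = sort(rest)))
    }
    stop("assignment-error: no species-complete bipartition found")
  }
  stop("assignment-error: unknown clade rule")
}

#' Run the full duplicate-gene analysis pipeline
#'
#' Executes the enabled stages in dependency order and returns a `run_report`
#' whose tables mirror the observed/null recombination summary, the
#' branch-site selection contrasts, the divergence indices and the per-clade
#' gamma statistics.  Identical config + seed reproduces the report.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return object of class `run_report`: list of per-stage tables plus a
#'   `provenance` block (seed, stages, package version, warnings).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  warns <- character(0)
  note <- function(w) warns <<- c(warns, w)
  if (!is.null(config$seed)) set.seed(config$seed)

  ca <- if (inherits(config$codon_fasta, "codon_aln")) config$codon_fasta
    else to_codon_alignment(read_fasta(config$codon_fasta),
                            allow_stops = TRUE)
  a <- ca$aln
  tree <- config$tree
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.null(tree)) {
    say("stage tree: NJ on p-distances")
    tree <- neighbor_joining(distance_matrix(a, "p"))
  }
  miss <- setdiff(tree$tip.label, rownames(a))
  if (length(miss))
    stop("validation-error: tree tips absent from alignment: ",
         paste(miss, collapse = ", "))
  rooted_tree <- if (ape::is.rooted(tree)) tree else phangorn::midpoint(tree)
  clades <- clade_assign(rooted_tree, config$clades)

  rep_tables <- list()

  if ("popgen" %in% config$stages) {
    say("stage popgen: diversity / recombination statistics")
    pg <- popgen_summary(a)
    pg$dataset <- "codon"
    if (!is.null(config$full_fasta)) {
      fa <- if (inherits(config$full_fasta, "aln")) config$full_fasta else
        read_fasta(config$full_fasta)
      pg2 <- popgen_summary(fa)
      pg2$dataset <- "full"
      pg <- rbind(pg, pg2)
    }
    rep_tables$popgen <- pg
  }

  if ("coalnull" %in% config$stages) {
    say("stage coalnull: coalescent null distributions (%d reps)", config$reps)
    ss <- segregating_sites(a)
    obs_rm <- four_gamete_Rm(ss)
    obs_zz <- zz_statistic(ss)$ZZ
    nd_rm <- null_distribution(
      coal_config(ss$n, ss$S, "free", reps = config$reps,
                  seed = config$seed + 1L),
      four_gamete_Rm, obs_rm, name = "Rm")
    nd_zz <- null_distribution(
      coal_config(ss$n, ss$S, "none", reps = config$reps,
                  seed = config$seed + 2L),
      function(s) zz_statistic(s)$ZZ, obs_zz, name = "ZZ")
    rep_tables$coalnull <- data.frame(
      statistic = c("Rm", "ZZ"), observed = c(obs_rm, obs_zz),
      null_mean = c(nd_rm$mean, nd_zz$mean),
      ci_low = c(nd_rm$ci_low, nd_zz$ci_low),
      ci_high = c(nd_rm$ci_high, nd_zz$ci_high),
      p_ge = c(nd_rm$p_ge, nd_zz$p_ge),
      p_ge_raw = c(nd_rm$p_ge_raw, nd_zz$p_ge_raw))
  }

  if ("gamma" %in% config$stages) {
    say("stage gamma: NG distance trees and gamma statistics")
    rows <- list()
    for (meth in c("NG-nonsyn", "NG-syn")) {
      dm <- tryCatch(distance_matrix(ca, meth), warning = function(w) {
        note(conditionMessage(w)); suppressWarnings(distance_matrix(ca, meth))
      })
      tr <- neighbor_joining(dm)
      for (cl in c("all", "dup1", "dup2")) {
        tips <- switch(cl, all = tr$tip.label, dup1 = clades$dup1,
                       dup2 = clades$dup2)
        sub <- if (cl == "all") tr else
          ape::keep.tip(tr, intersect(tips, tr$tip.label))
        g <- tryCatch(gamma_statistic(sub), error = function(e) {
          note(conditionMessage(e)); list(gamma = NA_real_, p = NA_real_,
                                          n = length(tips))
        })
        rows[[length(rows) + 1L]] <- data.frame(
          tree = meth, clade = cl, n = g$n, gamma = g$gamma, p = g$p)
      }
    }
    rep_tables$gamma <- do.call(rbind, rows)
  }

  if ("selection" %in% config$stages) {
    say("stage selection: M0 + branch-site model A contrasts")
    m0 <- fit_model(ca, tree, "M0")
    rows <- list(data.frame(model = "M0", foreground = "none", np = m0$np,
                            lnL = m0$lnL, two_delta_L = NA, p = NA,
                            omega_fg = m0$mles$omega))
    for (cl in c("dup1", "dup2")) for (mode in c("stem", "all")) {
      fgt <- intersect(clades[[cl]], m0$tree$tip.label)
      null <- fit_model(ca, m0$tree, "bsA-null", foreground = fgt,
                        foreground_mode = mode, restarts = 1L,
                        kappa = m0$mles$kappa, fix_kappa = TRUE)
      alt <- fit_model(ca, m0$tree, "bsA", foreground = fgt,
                       foreground_mode = mode, restarts = 1L,
                       kappa = m0$mles$kappa, fix_kappa = TRUE,
                       init_par = embed_init(null, "bsA"))
      ltr <- lrt(null$lnL, alt$lnL, 1L, boundary_mixture = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        model = "bsA", foreground = paste(cl, mode), np = alt$np,
        lnL = alt$lnL, two_delta_L = ltr$two_delta_L, p = ltr$p,
        omega_fg = alt$mles$omega2)
    }
    rep_tables$selection <- do.call(rbind, rows)
  }

  if ("codonusage" %in% config$stages) {
    say("stage codonusage: ENC / CBI by duplicate clade")
    grp <- setNames(rep(NA_character_, nrow(a)), rownames(a))
    grp[intersect(clades$dup1, names(grp))] <- "dup1"
    grp[intersect(clades$dup2, names(grp))] <- "dup2"
    cu <- codon_usage(ca, groups = grp)
    rep_tables$codonusage <- cu$table
    rep_tables$codonusage_groups <- cu$group_summary
    if (!is.null(cu$tests))
      rep_tables$codonusage_tests <- data.frame(
        index = c("ENC", "CBI"),
        p = c(cu$tests$ENC$p, cu$tests$CBI$p))
  }

  if ("divergence" %in% config$stages) {
    say("stage divergence: Gu type-I / type-II statistics")
    prot <- translate_alignment(ca)
    d1 <- intersect(clades$dup1, rownames(prot))
    d2 <- intersect(clades$dup2, rownames(prot))
    if (length(d1) >= 3L && length(d2) >= 3L) {
      pair <- cluster_pair(prot, d1, d2)
      t1 <- tryCatch(gu_type1(pair, boot = config$boot,
                              seed = config$seed + 3L),
                     error = function(e) { note(conditionMessage(e)); NULL })
      t2 <- gu_type2(pair, boot = config$boot, seed = config$seed + 4L)
      rep_tables$divergence <- data.frame(
        index = c("theta_I", "theta_I_ML", "theta_II"),
        estimate = c(if (is.null(t1)) NA else t1$theta_I,
                     if (is.null(t1)) NA else t1$theta_I_ML, t2$theta_II),
        se = c(if (is.null(t1)) NA else t1$se,
               if (is.null(t1)) NA else t1$se_ML, t2$se),
        z = c(if (is.null(t1)) NA else t1$z, NA, t2$z),
        p = c(if (is.null(t1)) NA else t1$p,
              if (is.null(t1)) NA else t1$p_lrt, t2$p))
      rep_tables$divergence_sites <- site_posterior_profile(t2)
    } else {
      note("divergence skipped: need >= 3 sequences per clade")
    }
  }

  structure(list(tables = rep_tables,
                 provenance = list(seed = config$seed,
                                   stages = config$stages,
                                   clades = clades,
                                   package = "dupsel",
                                   version = "0.1.0",
                                   warnings = warns)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("dupsel run report; tables:", paste(names(x$tables), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a run report as TSV tables plus a JSON index
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report$tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(report$tables[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(report$provenance, pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}

#' Translate a codon alignment to protein
#'
#' Gapped or ambiguous codons translate to `-`; stops to `*`.
#' @param ca a codon alignment.
#' @param code a [genetic_code()].
#' @return a protein [aln()].
#' @export
translate_alignment <- function(ca, code = genetic_code()) {
  cods <- codon_strings(ca)
  aa <- matrix(code$aa[cods], nrow = nrow(cods),
               dimnames = list(rownames(cods), NULL))
  aa[is.na(aa)] <- "-"
  aln(aa, type = "protein")
}
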