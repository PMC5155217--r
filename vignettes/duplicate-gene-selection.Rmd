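---
title: "Inferring the evolutionary fate of duplicated genes with dupsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the evolutionary fate of duplicated genes with dupsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupsel)
```

## The scientific problem

When a gene duplicates, the two copies can be lost, degrade into
pseudogenes, specialize on complementary parts of the ancestral function
(subfunctionalization), or acquire new functions under positive selection.
Distinguishing these fates from sequence data requires several independent
lines of evidence on the same gene-family alignment:

* **Recombination and neutrality statistics** on the sampled haplotypes —
  nucleotide diversity π, Watterson's θ_W, Tajima's D, Hudson's
  recombination estimator R, the Hudson–Kaplan minimum number of
  recombination events Rm, and the Za/ZnS/ZZ linkage-disequilibrium
  statistics — with coalescent null distributions to judge significance.
* **Codon-substitution likelihood models** (M0, free-ratio, the site models
  M1a/M2a and M7/M8/M8a, and branch-site model A) to locate positive
  selection (ω = dN/dS > 1) on specific duplicate clades and codons.
* **Gu's functional-divergence statistics**: type-I (θ_I, a shift in
  per-site evolutionary rates between duplicate clades) and type-II (θ_II,
  fixed radical biochemical differences between the clades' ancestors).
* **Codon-usage indices** (ENC, CBI) as a proxy for expression divergence.
* **Diversification-rate analysis** through lineage-through-time curves and
  the Pybus–Harvey γ-statistic on synonymous-only and nonsynonymous-only
  distance trees.

`dupsel` implements this entire battery as a tested, scriptable pipeline,
together with synthetic-data generators that produce every input class with
known ground truth, so each stage can be validated end to end without any
external download.

## Models and estimators

### Diversity and recombination

All alignment statistics mask gaps, `N` and IUPAC ambiguity codes as missing
data, pairwise where the statistic is pairwise. `S` counts all variable
sites (the Watterson definition, multiallelic included); the LD statistics
use biallelic sites only, coding alleles 0/1 and dropping rows with missing
data for each site pair. `ZZ = Za − ZnS` contrasts adjacent-pair LD with
all-pair LD; elevated values indicate intragenic recombination.

Hudson's R is estimated by the variance method: the observed variance of
pairwise difference counts `S_k²` is equated with its coalescent
expectation. We derive that expectation from the two-locus correlation of
pair coalescence times, `ρ(c) = (c+18)/(c²+13c+18)`, integrated over site
pairs:

$$E[S_k^2](C) = \frac{2n-4}{3(n-1)}\,\hat\pi +
  \Big(1 - \frac{2(n^2+n+3)}{9n(n-1)}\Big)\,\hat\pi^2\,\phi(C),
\qquad
\phi(C) = \frac{2}{C^2}\int_0^C (C-u)\,\rho(u)\,du .$$

The C = 0 limit reproduces Tajima's no-recombination variance of pairwise
differences, and φ decreases in C, so a larger excess variance yields a
smaller estimate. The root is found by bisection on C ∈ [10⁻⁶, 10⁴]
(tolerance 10⁻⁸); samples whose variance falls outside the attainable range
are reported at the nearest bound with an `at_bound` flag. The
per-adjacent-site rate divides by the number of analyzed sites.

The coalescent simulator conditions on a fixed number of segregating sites
(the observed S is the natural conditioning quantity when θ is unknown).
"Free recombination" draws every site on an independent genealogy; a finite
per-gene rate ρ runs a discrete-site ancestral recombination graph and
places mutations on the marginal trees. Monte-Carlo p-values are reported
both raw and with the add-one correction `(#{sim ≥ obs}+1)/(reps+1)`, so
the corrected p is never exactly zero.

### Codon models

The substitution process runs on the 61 sense codons: zero rate for
multi-nucleotide changes, target-codon frequency π_j for synonymous
transversions, κπ_j for synonymous transitions, and ω-scaled versions of
both for nonsynonymous changes. Codon frequencies default to F3x4 estimated
from the data (with a 10⁻¹⁰ floor against empty cells). Each class matrix
is normalized on a **common mixture-wide time scale**: branch lengths are
expected substitutions per codon averaged over site classes, so sites in a
class with larger ω genuinely evolve faster. Likelihoods use scaled
Felsenstein pruning over site patterns; the likelihood is invariant under
re-rooting, as the model is reversible.

Fitting proceeds in two regimes. M0 and the free-ratio model optimize
branch lengths jointly with the rate parameters by coordinate rounds
(Nelder–Mead on the rate parameters alternating with bounded quasi-Newton
on log branch lengths; rounds stop when the round-to-round improvement
drops below 10⁻⁴ log-likelihood units, with sub-optimizations at relative
tolerance 10⁻⁸). Site-class models by default hold branch lengths fixed at
an M0 fit on the same topology. This is a deliberate design choice: it
makes the nesting chains lnL(M2a) ≥ lnL(M1a), lnL(M8) ≥ lnL(M8a) ≥
lnL(M7) and lnL(bsA) ≥ lnL(bsA-null) exact (both members of each contrast
see identical branch lengths), stabilizes mixtures that are otherwise
multimodal, and keeps repeated fits fast; joint optimization remains
available via `optimise_branch_lengths = TRUE`. Nested alternatives should
be started from the null's solution with `embed_init()`, which also fixes
a one-evaluation floor so the alternative can never end below the null.
M7/M8/M8a discretize the beta distribution into K = 8 equal-probability
categories represented by quantile midpoints — a package default chosen as
the smallest K at which the beta-family fits were indistinguishable on our
synthetic data from finer grids.

The branch-site test compares model A with its ω2 = 1 null; because the
null pins ω2 at the boundary, the default p-value uses the 50:50 mixture
of a point mass at zero and χ²₁ (the printed χ²₁ value is also reported —
it is conservative). Site posteriors are naive empirical Bayes; Bayes
empirical Bayes is not implemented and outputs are labeled accordingly.

Topology comparison (the duplication-before vs duplication-after-speciation
question) uses per-topology M0 fits, followed by RELL bootstrap of the
per-site log-likelihood vectors (default 10,000 resamples) for the KH and
SH tests; the AU test is out of scope.

### Functional divergence

Type-I divergence works on per-site substitution counts obtained from
marginal maximum-likelihood ancestral reconstruction under a Poisson
(equal-rates) amino-acid model — a deterministic, assumption-light choice;
a Fitch parsimony fallback is available. The model-free estimator corrects
the between-clade count correlation for Poisson sampling noise
(`θ_I = 1 − cov(X,Y)/√((var X − mean X)(var Y − mean Y))`); the ML
estimator fits a two-class mixture (shared gamma rate vs independent rates,
negative-binomial marginals) with an LRT against θ_I = 0. Standard errors
are site-bootstrap based (500 replicates by default).

Type-II divergence compares the two clades' ancestral sequences site by
site. A change is **radical** if it crosses the charge partition
{D,E | K,R,H | rest} or the hydropathy partition (sign of the
Kyte–Doolittle index: A,C,F,I,L,M,V hydrophobic); the partition is fixed,
symmetric and configurable. With F00 denoting sites with no within-clade
change, observed F00 proportions P_C (conserved) and P_R (radical), and
π_R the neutral radical proportion (the fraction of radical changes among
all single-nucleotide nonsynonymous codon changes, computed from the
genetic code), the estimator is

$$\hat\theta_{II} = P_R - \frac{\pi_R}{1-\pi_R}\,P_C ,$$

i.e. conserved changes are attributed to nonfunctional divergence at
neutral radical odds, and type-II sites are modeled as always radical.
`z = θ_II/SE` with a 1000-replicate site bootstrap SE. Estimates outside
[0, 1] are flagged, never silently clamped. The per-site posterior ratio
uses the fitted mixture; the identity ratio = p/(1−p) holds exactly, so a
ratio above 4 is a posterior above 0.8.

### Codon usage and diversification

ENC follows Wright's homozygosity construction with the standard-code
family counts (2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆), families with fewer
than two observations skipped, a missing F̄₃ imputed as the mean of F̄₂ and
F̄₄, and values clamped at 61; Met, Trp and stops are excluded. CBI needs
an optimal-codon set: supplied explicitly, or inferred as the modal codon
per amino acid over the pooled input with alphabetical tie-breaking, so
runs are reproducible. Group contrasts use Welch's t-test by default (the
pooled-variance Student variant sits behind a flag), with `t = 0, p = 1`
when both groups are constant and equal.

The γ-statistic follows the internode-interval formula and is standard
normal under a constant-rate pure-birth process. The substitution-distance
NJ trees this package builds (Nei–Gojobori synonymous-only or
nonsynonymous-only proportions) are not ultrametric, so γ is computed
after midpoint rooting and node-depth averaging (each internal node's age
is the mean of its node-to-tip paths, clamped below the parent's age) —
a rate-smoothing-free choice exposed behind `ultrametricize`, with raw
depths available when disabled. Negative NJ branch lengths are clamped to
zero with the deficit moved to the sister branch, which keeps path lengths
additive and the LTT curve valid.

## What the synthetic generators emulate — and what they do not

`simulate_tree()` draws Yule or birth–death trees conditioned on the tip
count; `simulate_duplication_gene_tree()` builds gene trees in which a
duplication either precedes speciation (two mirrored species clades) or
follows it (species-local cherries); `simulate_codon_alignment()` evolves
codons by exact Gillespie simulation so realized per-branch
synonymous/nonsynonymous counts are available as ground truth;
`simulate_radical_bias()` forces a chosen fraction of sites into opposite
charge classes between two clade ancestors. Defaults follow the study
conditions the pipeline targets: duplicate clades of 3–5 species, a few
hundred codons, background ω around 0.2–0.3, foreground ω up to 5 on a
tenth of sites, 255-site protein alignments for the divergence tests.

The generators deliberately omit several features of real data: no indels
or alignment error, no intron evolution, no rate heterogeneity beyond the
modeled site classes, no base-composition drift, and no sequencing or
cloning artifacts. Green calibration tests therefore demonstrate that the
estimators are correct and well calibrated **under the model**, not that
real alignments satisfy the model.

## Numerical choices and degenerate inputs

* Likelihood underflow is prevented by per-node rescaling of partial
  likelihoods; site likelihoods are floored at 10⁻³⁰⁰ before logging.
* The reversible rate matrix is diagonalized through its symmetric
  similarity transform; decompositions are memoized on (κ, ω, π), which
  makes branch-length optimization phases cheap.
* Tajima's D is undefined at S = 0 and reported as missing, not zero;
  Hudson's R is undefined below S = 2; ZZ below two biallelic sites.
* ω on branches with dS = 0 in counting reports is flagged infinite rather
  than replaced by a sentinel.
* Ties in ancestral-state posteriors resolve to the first state in a fixed
  residue order; NJ tie-breaking sorts labels first. Identical topologies
  in the KH test give p = 1 by construction.
* Every stochastic routine takes an explicit seed, and the pipeline
  requires one whenever a stochastic stage is enabled; identical
  configuration and seed reproduce reports bit for bit.

## Problem sizes used by the test and acceptance suites

The validation suites simulate at sizes chosen to exercise each property
clearly: 2000 coalescent replicates for the neutrality calibrations
(n = 10, S = 20 for D; n = 25, S = 40 for ZZ); 20 replicates of 5-taxon,
400-codon alignments for M0 recovery; 15–20 replicates of 6-tip,
300-codon alignments for branch-site power (foreground ω₂ = 5) and size,
with branch lengths held at the generating tree and κ at its true value so
the experiment isolates the LRT machinery; 500 Yule trees (n = 30) for γ;
20 replicates of 255-site alignments for type-II recovery; and 10–20
replicates of 500-codon alignments for topology-test power.

## Known limitations

* The branch-site and site-model fits assume the supplied topology is
  correct; topology error shows up as inflated foreground ω estimates.
* The type-II estimator presumes ancestral states are reconstructed
  correctly at F00 sites; at high within-clade divergence the F00 class
  shrinks and the bootstrap SE grows accordingly.
* The ML type-I mixture treats clade rates as site-independent
  gamma-distributed; strong among-site autocorrelation would mis-calibrate
  the LRT.
* DnaSP's historical CBI depends on an organism-specific optimal-codon
  table; with the modal-codon inference rule used here, absolute CBI values
  are comparable within a run but not across tools.

## A minimal end-to-end run

```{r, eval = FALSE}
tr <- simulate_duplication_gene_tree(
  dup_scenario(4, "before-speciation", dup_branch = 0.3), seed = 1)
sim <- simulate_codon_alignment(tr, 300, kappa = 2, omega = 0.25, seed = 2)

cfg <- run_config(sim$ca, tree = tr, clades = "suffix",
                  reps = 1000, boot = 500, seed = 3)
report <- run_pipeline(cfg)
report$tables$popgen
report$tables$selection
write_report(report, "dupsel_run")
```
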