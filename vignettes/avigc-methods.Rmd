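---
title: "Methods: life history, recombination and avian base composition"
author: "avigc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: life history, recombination and avian base composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avigc)
```

## The scientific question

GC-biased gene conversion (gBGC) is a recombination-associated repair bias
that favors the transmission of G/C alleles in A:C and G:T heteroduplexes.
Because a favored allele behaves as if positively selected, the efficacy of
gBGC grows with effective population size (Ne), and because it acts once
per meiosis, its pace per unit time grows as generation time shrinks.
Species with small bodies — typically large Ne and short generations —
are therefore expected to accumulate GC faster, most visibly at
weakly-constrained sites: third codon positions (GC3) and introns (GCi).
Birds are a favorable system: their karyotype and broad-scale recombination
landscape are unusually stable, so between-lineage differences in
composition reflect life history rather than chromosomal turnover, and
their many micro-chromosomes guarantee high crossover rates on small
chromosomes.

`avigc` implements the complete analysis chain for this hypothesis:

1. **Composition** — GC by codon position and for introns, per ortholog and
   pooled per species (counts summed before dividing, so short sequences do
   not add noise); ranking of orthologs by between-species GC3 variance; a
   contingency-test classifier for compositional homogeneity.
2. **Trait statistics** — Spearman/Kendall rank correlations with exact
   small-sample p-values, phylogenetically independent contrasts,
   a gene-subset randomization test, Wilcoxon rank-sum comparisons, and the
   time-corrected GC3 conservation index gamma.
3. **Coalescent Ne** — species-tree branch lengths in coalescent units from
   gene-tree discordance (n12/nkk lineage counts), and ancestral effective
   population sizes from internodal time spans and generation times.
4. **Substitution mapping** — a T92 substitution model fitted by maximum
   likelihood on a fixed tree, expected W→S and S→W counts per branch, and
   the equilibrium composition GC3*.
5. **Recombination windows** — joins of ortholog statistics to fixed-width
   recombination-map windows and chromosome size classes.
6. **gBGC dynamics** — the approach of GC to its equilibrium, with a
   population layer built on the Kimura fixation probability.
7. **Synthetic data** — a generator producing every input the pipeline
   consumes, with the statistical structure the analysis assumes.

## Composition conventions

GC fractions are computed as GC/(GC+AT) over the selected columns; gaps and
N are excluded from numerator and denominator, and a codon containing a gap
still contributes its non-gap positions. A species with zero counted sites
is a flagged missing value, never 0. Pooled per-species values sum counts
across orthologs before dividing (length-weighted); the tests verify this
equals counting on physically concatenated sequences. The GC123 count
identity (GC123 counts = GC1+GC2+GC3 counts) holds exactly on every input.

The variance ranking uses the per-ortholog between-species sample variance
of GC3 (denominator n−1), with lexicographic ortholog-id tie-breaks so the
top-k/bottom-k split is deterministic. The default split size mirrors the
830/830 convention of large avian ortholog sets but is a parameter.

The homogeneity classifier is deliberately light-weight: a chi-square
contingency test of species × {strong, weak} counts at third positions
(df = number of species − 1). It is an interface-compatible stand-in for a
full nonstationary-vs-stationary likelihood-ratio machinery, which is out
of scope here; the label field and alpha threshold are the same, so a
likelihood-based classifier can be slotted in later. Because neighboring
species share ancestry, the test is conservative when divergence is
shallow; its size is checked in the tests on deep-divergence simulations
where species are effectively exchangeable.

## Rank statistics and gamma

Spearman and Kendall correlations drop incomplete pairs and use average
ranks / tau-b for ties. For nine or fewer tie-free pairs the two-sided
p-value is exact: Spearman by direct enumeration over all permutations,
Kendall through the inversion-count distribution (identical to full
enumeration). The Wilcoxon rank-sum test is exact by enumeration when both
samples have at most eight tie-free observations and uses the tie- and
continuity-corrected normal approximation otherwise.

The time-corrected GC3 conservation index for a species pair is
gamma = −t / log(tau), with t the divergence time and tau the Kendall
(tau-b) correlation of per-gene GC3 between the two species. The log is
natural — the choice only rescales gamma by a constant, and units of t pass
through, so gamma is comparable within a run but not across time units.
Because tau is rank-based, gamma is exactly invariant under strictly
monotone transformations of either species' values. tau ≤ 0 leaves gamma
undefined (no conservation signal); tau = 1 gives +Inf, flagged. Pair
selection (disjoint pairs, exclusions, a minimum divergence time,
preference for deeper splits) is policy, implemented as a configurable
helper, not hard-wired.

The subset randomization test draws gene subsets without replacement and
reports the one-sided empirical p with the add-one correction
(r+1)/(n+1), so "none of 10,000 randomizations" is reported as
p < 1/10,001 rather than 0.

Phylogenetically independent contrasts delegate to `ape::pic` (the
package's own recursive implementation exists only as a test oracle), and
correlations between two traits' contrasts are forced through the origin.

## Coalescent branch lengths and ancestral Ne

For each internal species-tree branch, n12 counts gene trees with one
lineage at the rootward end and two at the tipward end (coalescence inside
the branch) and nkk counts trees with k ≥ 2 lineages at both ends (no
coalescence; all k pooled). The branch length in coalescent units is
log((n12+nkk)/nkk), the maximum-likelihood inversion of the non-coalescence
probability e^−T for two entering lineages.

Two reconciliations are provided. The **topological** route (`"lca"`) maps
each gene node to the smallest species clade containing its descendants.
It is the procedure usually applied to undated gene trees, but it cannot
see a *hidden deep coalescence*: a cherry pair that fails to coalesce
inside its branch yet still coalesces directly with each other higher up
maps back to the same branch. For three taxa the observable
non-coalescence fraction is then (2/3)e^−T — exactly the classic
discordant-topology probability — and the estimator recovers T + log(3/2)
rather than T. The **temporal** route uses node times: when gene trees are
ultrametric on the same time axis as the species tree (dated gene trees;
the package's own simulator emits them), each coalescence is placed in the
species branch whose time interval contains it, the hidden cases are
resolved, and the estimator is unbiased. `"auto"` (the default) uses
temporal mapping whenever both trees carry usable heights. Both behaviors
are pinned by tests against closed-form expectations.

Unresolved gene-tree nodes are treated as failures to coalesce within the
branch they map to (they enter nkk) — a conservative choice. Gene trees
missing species contribute only to branches with at least one sampled
species on each descendant side. Terminal branches are reported undefined:
with one lineage per species they carry no coalescence information.

Ancestral effective size for a branch is
N = time span / (2 × coalescent length × generation time), with generation
time the mean of the values at the branch ends; age at first female
maturity is the default proxy for generation time (survival-based
corrections tend to produce generation times exceeding longevity in
late-reproducing birds). Downstream filters default to coalescent length
≥ 0.1, node support ≥ 50, and cherry branches only — sizes for terminal
branches are undetermined and for the very short deep branches unreliable.
The outputs carry a rank column: these reconstructions are rank-order
quantities, systematically inflated when generation time is underestimated.

## T92 fitting and substitution mapping

The Tamura (1992) model is parameterized by the equilibrium GC content
theta and the transition/transversion ratio kappa; stationary frequencies
are fG = fC = theta/2, fA = fT = (1−theta)/2, and the rate matrix is scaled
to one expected substitution per site per unit branch length. Transition
probabilities use the closed two-eigenvalue form (verified against a
generic matrix exponential to 1e-10). The fit maximizes the pruning
likelihood over (theta, kappa), optionally with a global branch-length
scale, by bounded L-BFGS-B from fixed starts (theta = observed GC,
kappa = 2, tolerance ~1e-9 on the log-likelihood), so it is deterministic
given the data. Site patterns are compressed before fitting. Rate
heterogeneity across sites and CpG hypermutability are not modeled.

Expected W→S and S→W counts per branch come from inside–outside passes.
The default `"endpoint"` rule books the joint posterior probability of a
weak parent and strong child state (and vice versa); it slightly
undercounts multiple hits on longer branches. The `"integrated"` mode
computes the analytic expected number of labeled substitutions
(quadrature over the transition kernel) and also counts reversals; both
are validated against an event-logging simulator.

**GC3\*** is the composition expected on an infinitely long branch. The
package computes it as the equilibrium of the two-state weak/strong
dynamic, u/(u+v), where u is the W→S rate per weak site and v the S→W rate
per strong site, obtained by normalizing branch counts with the branch's
expected class occupancies. This normalization matters: the plain ratio of
summed raw counts equals 1/2 for any reversible model at compositional
equilibrium (class fluxes balance), so it cannot estimate equilibrium GC;
the rate-normalized ratio equals theta exactly at stationarity. The raw
count ratio remains available (`normalize = FALSE`) for comparison with
summed-count conventions. Per-species GC3* sums counts and exposures over
the root-to-tip path by default (`per_tip_root_path`); `per_branch` covers
analyses that average the equilibrium at the two ends of a branch.

Under a recent shift of terminal-branch equilibria from 0.40 toward 0.55,
GC3* tracks the new equilibrium while GC3 lags, so GC3* > GC3 for nearly
every tip, and the regression slope of GC3* on GC3 exceeds 1 by roughly
1/(1 − e^−r t) with r the relaxation rate and t the terminal branch length
— the compression mechanism behind steep GC3*-on-GC3 slopes in birds.

## gBGC dynamics

With per-generation substitution rates u (W→S per weak site) and v (S→W
per strong site), GC follows g(t) = g* + (g0 − g*)e^−(u+v)t with
g* = u/(u+v); the time to halve the distance to equilibrium is
ln 2/(u+v), independent of g0. The population layer derives
u = 2 Ne mu_WS P_fix(Ne, +b) and v = 2 Ne mu_SW P_fix(Ne, −b), with the
Kimura-form fixation probability P = (1−e^−2b)/(1−e^−4Ne b) for a new
mutant under conversion coefficient b (haploid-equivalent bookkeeping with
2Ne copies; the diploid constant cancels in the half-life). The defaults
used in examples — mu_WS = 1e-9, mu_SW = 2e-9 per generation (an AT-biased
mutation spectrum), b = 5e-7 — give half-lives near 2.4e8 generations for
Ne between 1e5 and 1e6, i.e. far beyond the age of the avian radiation,
which is why present-day GC3 is expected to sit below GC3*.

## What the synthetic data emulate

The generator produces every input the pipeline reads, under one master
seed split into named substreams (so adding genes does not perturb trait
draws). Defaults define the package's standard study conditions:

* 40 species on a 100-My ultrametric tree whose node heights are pushed
  toward the root (power 0.3) — a radiation with short deep internodes and
  long terminal branches, converted to substitutions at 0.002
  substitutions/site/My (root-to-tip ≈ 0.2).
* Body mass log-normal (median ~300 g, an order of magnitude spread);
  age at first maturity and longevity scale as mass^0.25 and mass^0.2 with
  log-normal noise; generation time is proxied by age at first maturity;
  branch Ne scales as mass^−0.3 around 5e5.
* 1,500 coding orthologs of 300 codons and 404 introns of 500 bp. Third
  positions evolve under branch-specific T92 (kappa 2): ancestral
  equilibrium theta 0.42 on internal branches; on the terminal branch of
  species s, gene g has theta = 0.42 + m_g(0.08 + dev_s + eps), where
  dev_s is a noisy-rank mass deviation of spread ±0.1 (small-bodied
  positive), eps is N(0, 0.02) gene-by-species noise, and m_g is the
  gene's recombination multiplier. First/second positions evolve with the
  theta range compressed toward 0.5 by 0.15, reproducing the narrow
  GC1/GC2 ranges of constrained sites.
* A karyotype of 9 large (40–190 Mb) and 19 small (5–20 Mb) chromosomes in
  1-Mb windows; chromosome rate = 0.8 + 60/size_Mb cM/Mb (one obligate
  crossover), two maps drawn as log-normal observations of a shared
  window rate with the shared-noise weight solved to approximate a
  cross-map rank correlation of 0.4; m_g is the gene's window's shared
  rate normalized to mean 1.
* Gene trees from the multispecies coalescent with branch lengths
  time span/(2 Ne g), emitted time-calibrated.

These choices make the qualitative findings detectable at desk scale: a
strongly negative mass–GC3 correlation, higher GC3 variance and median on
small/high-recombination chromosomes, GC3* above GC3 in essentially all
tips, and informative levels of gene-tree discordance. Every coupling has
a null switch (`mass_effect = 0`, `terminal_shift = 0`, zero noise terms)
used for type-I-error calibration of the downstream tests.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: codon structure and selection (positions
are simulated independently; no amino-acid constraint), indels and
alignment error, CpG hypermutability, rate heterogeneity across sites,
within-genome isochore spatial autocorrelation beyond the window-level
multiplier, missing data patterns of real assemblies, and measurement
error in life-history tables. Trait values are drawn independently across
species (no phylogenetic inertia in mass), so the contrasts machinery is
exercised on Brownian traits only in the tests.

## Numerical choices and degenerate inputs

* Exact rank-test enumeration switches to asymptotics above n = 9 (ties:
  always asymptotic, flagged).
* The T92 fit refuses to report a likelihood optimum when the optimizer
  signals non-convergence; alignments without variable sites short-circuit
  to the observed-frequency theta with a warning.
* Zero-length branches get identity transition matrices; expected-count
  quadrature returns zero counts there.
* GC3* is undefined (flagged) when no substitutions are expected or a
  class exposure is zero; coalescent lengths are +Inf when nkk = 0 and NA
  when a branch is uninformative; Ne is undefined for zero/infinite
  lengths.
* Ties in the variance ranking and window assignment (equal overlap) are
  broken deterministically (lexicographic id; lower window start).
* The per-generation fixation probability is overflow-guarded on both
  tails (log-space for 4Ne|b| > 700).

## Problem sizes used in the checks

The packaged checks run at the sizes the analyses are designed for:
10,000 gene trees for coalescent-length and Ne recovery (grid
T ∈ {0.2, 0.5, 1, 2}; 8 cherry branches), 50,000 third positions across 20
tips for GC3* stationarity/nonstationarity, 30,000 logged sites across 10
tips for the substitution-count cross-validation, 100 replicate datasets
per arm (effect on/off) at the default 40 species × 1,500 genes for the
trait-correlation power and size study, and 200,000 Wright–Fisher
replicates for the fixation-probability check. Module-level property tests
use smaller replicate counts with binomial error bands computed at the
size actually run.

## Known limitations

The homogeneity classifier is a contingency stand-in, conservative under
shallow divergence. The topological lineage-counting route inherits the
hidden-deep-coalescence bias discussed above and is retained for parity
with undated-gene-tree practice; prefer dated gene trees and temporal
mapping where possible. GC3* inherits any misfit of the homogeneous T92
model (no CpG, no rate heterogeneity). Ancestral Ne values are rank-order
quantities. The pipeline assumes one sampled haplotype per species per
gene.
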