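---
title: "How many individuals does a population sample need? Methods behind scotdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many individuals does a population sample need? Methods behind scotdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scotdiv)
```

## The problem

Germplasm surveys with dominant molecular markers (SCoT, ISSR, RAPD, AFLP)
score each reproducible amplified fragment — a *band* — as present (1) or
absent (0) in each individual. Because heterozygotes are indistinguishable
from dominant homozygotes, all downstream statistics work directly on band
frequencies. A recurring design question is sample size: how many
individuals must be drawn from one population (an *accession*) so that the
sample retains most of the population's band diversity? Sampling too few
individuals loses alleles; sampling too many inflates the cost of
maintaining and regenerating stored germplasm.

`scotdiv` implements the complete analysis used to answer that question
for a four-accession, 60-individuals-per-accession, five-primer design:
diversity statistics, random-subsampling retention curves backed by an
exact rarefaction expectation, AMOVA differentiation, Jaccard/UPGMA
clustering with band-bootstrap support, and a model-based admixture
clustering with Evanno delta-K selection of the cluster number. A
synthetic-data generator with recorded ground truth makes every stage
testable without access to any particular laboratory data set.

## Data model

A `band_matrix` holds the 0/1 score matrix plus a population label per
individual and a primer label per band. Matrices are assumed
post-curation: only reproducible bands are scored, so a missing cell is a
hard error, never imputed. Files use a simple delimited layout (two header
rows for band ids and primers, an optional third for fragment sizes) that
round-trips exactly.

## Diversity statistics

All frequency-based statistics derive from the per-band presence counts
`c_b` among the `n` evaluated individuals.

* **Pooled band-as-allele frequencies.** Every observed band is treated
  as one allele of a single phantom multi-allelic locus with frequency
  `p_b = c_b / sum(c)`. This occurrence-proportional definition is pinned
  by its single-individual anchor: one individual showing `Na` bands has
  uniform frequencies, hence `He = 1 - 1/Na` (67 bands gives 0.9851 to
  four decimals). No `n/(n-1)`-type small-sample correction is applied —
  such corrections are undefined exactly at the `n = 1` anchor.
* **He** = `1 - sum(p^2)`; **PIC** is Botstein's multi-allelic form
  `1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`, evaluated through the
  identity `sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4` and verified
  in the tests against an explicit double loop. PIC never exceeds He.
* **PPB** counts a band as polymorphic when `0 < c_b < n`; the
  denominator is the number of bands observed in the same subset.
* **Shannon index** is the mean per-band binary entropy over the matrix's
  band universe; fixed and absent bands contribute zero, so the index
  lives in `[0, log 2]`.
* **Resolving power** of a primer is `Rp = sum_b (1 - 2 |0.5 - q_b|)`
  over the primer's bands, with `q_b = c_b / n`; it is maximal when every
  band sits at frequency one half.

Statistics over "all primers" pool bands across primers; the per-primer
tables restrict to each primer's own bands. He and PIC are reported to 4
decimals and reserve percentages as whole percents, matching field
convention.

## Retention curves and the exact rarefaction oracle

The core experiment subsamples each population at the ladder sizes
1, 2, 3, 5, 8, 10, 20, 30, 40, 50, 60 (dense where the curve bends,
sparse on the plateau), drawing uniformly **without replacement** —
which is why the curve reaches the full-sample band count exactly at
`n = N`. Each subsample is scored for its band count `Na`, the **reserve
percentage** `RP = 100 * Na(sub) / Na(full)` (rounded to whole percent,
ties away from zero), He and PIC. The reference `Na(full)` is the
accession's own 60-individual sample, not the pooled union, since
retention is a within-population question.

Monte-Carlo means are checked against a closed form: under simple random
sampling without replacement the expected subsample richness is

```
E[Na(n)] = sum_b ( 1 - choose(N - c_b, n) / choose(N, n) )
```

the hypergeometric probability that at least one carrier of each band is
drawn. The package computes this with `lchoose` for stability; the test
suite verifies it by exhaustive enumeration of all subsets on an
8-individual fixture and requires 500-replicate Monte-Carlo means to sit
within three standard errors of it at every ladder size.

The number of draws per ladder size is a free design choice (a published
table of single integers cannot distinguish one draw from a summary); the
default is 200 replicates reported as mean and SD, and `replicates = 1`
reproduces a single-draw design. `plateau_size()` reads off the smallest
ladder size whose mean RP reaches a threshold — 90% in the headline
analysis, where saturation is expected near ten individuals.

## AMOVA and the fixation index

For binary profiles the squared Euclidean distance between two
individuals is their band mismatch count, the standard AMOVA distance for
dominant data. The one-level decomposition uses the classical identities
`SS_total = sum_{i<j} d2_ij / N` and, per group,
`SS_within = sum_{i<j in g} d2_ij / n_g` (equal to centroid deviations by
Gower's identity — the test suite exploits exactly that equivalence as an
independent route, and cross-checks the partition against
`vegan::adonis2`). Variance components follow the mean-square equations
with the usual unequal-size coefficient `n0`;
`Phi_ST = s2_among / (s2_among + s2_within)` with a negative among
component reported as-is but clamped to zero inside the ratio. A
two-level "among species" stratum is omitted: with a single species it is
vacuous, and the grouping argument still accepts any partition.
Significance uses label permutations with the add-one estimator
`p = (1 + #{perm >= obs}) / (1 + B)`, default `B = 999`.

The fixation-index sweep subsamples every population at each ladder size
and reports Phi_ST per size. Because a per-accession fixation index is
not defined for a between-population quantity, the sweep offers two
explicit contrasts — each focal accession against the pooled others
(`"focal"`, one column per accession) or a single global among-all value
(`"global"`) — and reports size-1 rows as zero by convention (one
individual per group leaves no within-group degrees of freedom).

## Clustering

Jaccard similarity `a / (a + b + c)` ignores shared absences, the right
choice for dominant markers where absence of a band is not evidence of
relatedness. UPGMA is implemented directly so that its tie-break rule is
explicit and platform-stable: exact distance ties merge the smallest
(row, column) pair of the working matrix. Node heights are half the merge
distance, so the tree is ultrametric and cophenetic distances (twice the
MRCA height) reproduce an already-ultrametric input exactly. The
implementation is verified against both `stats::hclust(method =
"average")` and an O(n^4) oracle that recomputes every cluster distance
from the original leaf pairs.

Bootstrap support resamples **bands** (columns) with replacement —
individuals are the tree's tips, bands are the characters — rebuilds the
tree, and counts recovery of each original clade. Supports below 50% are
retained in the data structure but flagged as unreported when rendering,
the usual display convention. The replicate count defaults to 1000. A
band-resampled profile can become all-zero; inside the bootstrap such a
profile is treated as identical to other empty profiles and maximally
distant from non-empty ones, a closed-world convention that never occurs
on the user-facing path (where an all-zero individual is an error).

## Admixture model and delta-K

The model-based clustering is a purpose-built Gibbs sampler, not a
wrapper around any external program: individual `i` has membership
`q_i ~ Dirichlet(1)`; each band score originates from a latent cluster
`z_ij ~ Categorical(q_i)` and is `Bernoulli(theta[z_ij, j])` with a
uniform Beta prior on `theta`. Modelling bands directly as Bernoulli
characters (rather than reconstructing recessive genotype frequencies)
matches how a 0/1 matrix is actually scored and keeps the sampler fully
conjugate; the Dirichlet concentration is fixed at 1 and not inferred.
The traced `L(K)` is the observed-data mixture log-likelihood at the
state entering each sweep; its post-burn-in mean feeds the Evanno
statistic `delta_K = mean_r |L_r(K+1) - 2 L_r(K) + L_r(K-1)| /
sd_r(L_r(K))`, with runs paired by index. The supported cluster number is
the interior argmax (ties toward smaller K); a perfectly linear
likelihood profile or a zero run-to-run spread is flagged as "no signal"
rather than silently returning a K. When likelihood and delta-K point to
different K, delta-K is authoritative in this package.

Sampler defaults are desk-scale — 2,000 sweeps with 500 burn-in, grids of
K = 2..8 with 10 runs each — and the classical 100,000 + 10,000 settings
remain available through the same arguments. At the default scale a
K = 4 grid over K = 2..6 with 5 runs completes in under a minute on one
core for a 240 x 122 matrix, which is what makes the ten-master-seed
recovery test feasible.

## The synthetic generator: what it emulates, and what it does not

`generate_band_matrix()` emulates the statistical structure the analysis
assumes: four populations of 60 individuals scored at five primers
totalling 122 bands (25/21/29/23/24 per primer). Each population's band
probabilities combine

* shared **common** bands (ancestral frequency uniform on 0.35–0.65),
* shared **rare** bands (uniform on 0.02–0.15, a fraction
  `rare_fraction = 0.15` of shared bands),
* `private_band_count = 6` bands per population carried nowhere else, and
* a `divergence = 0.45` Balding–Nichols draw around the ancestral
  frequency for common bands, clipped to `[0.18, 0.95]` so that a shared
  common band stays observable, and polymorphic, in every population.

The defaults were chosen once, jointly, so that the generated data sit
where this kind of dominant-marker study sits: the exact expected reserve
percentage at `n = 10` falls in `[88, 97]` (retention saturating near ten
individuals), the realized AMOVA Phi_ST falls in the plausible
differentiation band `[0.2, 0.5]`, per-accession primer resolving powers
span roughly 3–14, and per-population observed band counts land near
100–105 out of 122. Private bands alone cannot produce realistic
differentiation (they yield Phi_ST below 0.1), which is why the
divergence parameter exists; conversely, an unbounded divergence draw
drives too many common bands rare within single populations and drags
retention at `n = 10` below where a saturating design sits, which is why
the clip bounds exist and why the default rare fraction is lower than a
naive reading of "30% of bands look rare on a gel" would suggest.
`calibrate_to_saturation()` makes the retention target explicit: it
checks a spec's exact expected RP at the target size and lowers
`rare_fraction` in deterministic steps until the band is met, warning
instead when a spec saturates trivially.

Deliberate non-features: bands are independent (no linkage — every
statistic here is single-band or frequency-based), there is no
mutation/drift forward simulation, and selfing/homozygosity is not
modelled explicitly because dominant 0/1 scoring already collapses
genotype state. Passing tests on this generator therefore demonstrate
correctness of the statistical machinery under the stated frequency
model, not robustness to linkage disequilibrium, scoring error, or
non-equilibrium demography in real data sets.

The ground truth (`truth$prob`, realized band counts, private band lists,
true population number) is returned alongside every matrix for
parameter-recovery tests.

## Numerical and reproducibility choices

* Rounding of reported percentages and 4-decimal statistics is
  half-away-from-zero (`round_half_up()`), not banker's rounding.
* `choose` ratios in the rarefaction oracle go through `lchoose`
  differences; an impossible subsample (`n > N - c_b`) contributes
  retention probability 1 via `exp(-Inf) = 0`.
* Every stochastic function takes an explicit seed; there is no
  wall-clock seeding anywhere. The pipeline derives per-stage child
  seeds deterministically from one master seed, so identical configs
  produce byte-identical tables, and library calls restore the caller's
  RNG state.
* The Gibbs sampler uses R's own RNG inside C++, so seeds behave
  identically across platforms; `theta` is clamped to
  `[1e-12, 1 - 1e-12]` to keep it strictly inside the open unit
  interval.
* UPGMA ties break lexicographically; bootstrap clade counting uses
  `ape::prop.clades` on rooted trees.

## Problem sizes used in the shipped checks

The test suite runs the full design (240 x 122) for single-pass checks
(AMOVA, tree cut, generator structure) and scales stochastic checks to
what one core handles comfortably: 500 rarefaction replicates for the
oracle comparison, 150-replicate bootstraps on 16-leaf fixtures, and a
delta-K recovery grid of K = 2..6 with 5 runs of 2,000 sweeps repeated
over ten master seeds. The full-scale admixture settings (K up to 8, 10
runs, 100,000 sweeps) are available but are a cluster-scale computation,
not part of the default checks.

## Known limitations

* The pooled band-as-allele frequency definition is one of several used
  in the dominant-marker literature; per-locus codominant estimators
  (Hardy–Weinberg back-calculation from band absence) are out of scope.
* The admixture sampler has no label-alignment across runs (no
  CLUMPP-style post-processing) and no correlated-frequency or linkage
  model; `L(K)` comparisons are unaffected, but per-run membership
  matrices may permute cluster indices.
* A per-accession fixation index at a given sampling size is reported
  under two explicit contrasts because the quantity is otherwise
  underdefined; the two modes answer different questions and are not
  interchangeable.
* Bootstrap supports on highly tied distance matrices depend on the
  deterministic tie-break; this is intended (reproducibility) but means
  support values on degenerate data should not be over-interpreted.
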