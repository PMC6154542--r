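# scotdiv

Sampling-size optimization and diversity analysis for dominant
presence/absence molecular markers (SCoT, ISSR, RAPD, AFLP band
profiles).

## The problem

When a germplasm survey scores each amplified band as present (1) or
absent (0) per individual, a central design question is how many
individuals must be sampled from one population (accession) so that the
sample retains most of that population's band diversity. Too few
individuals lose alleles; too many inflate the cost of conserving and
regenerating stored seed. `scotdiv` answers this with retention curves:
subsample each population at increasing sizes *n*, track the **reserve
percentage** `RP(n) = 100 · Na(subsample) / Na(full sample)` (the share
of the full sample's bands retained), and read off the smallest *n*
whose retention clears a threshold such as 90%.

The Monte-Carlo curves are anchored by an exact rarefaction oracle: for
a population of *N* individuals in which band *b* is carried by `c_b`
individuals, a uniform subsample of size *n* (without replacement) has
expected band count

    E[Na(n)] = Σ_b ( 1 − C(N − c_b, n) / C(N, n) )

Around this core the package implements the complete analysis of a
multi-accession dominant-marker study:

* **Diversity statistics** on pooled band-as-allele frequencies
  (`p_b = c_b / Σ c`): observed band number Na, percentage of polymorphic
  bands, expected heterozygosity `He = 1 − Σ p²`, Botstein's
  polymorphism information content
  `PIC = 1 − Σ p² − Σ_{i<j} 2 p_i² p_j²`, Shannon information index,
  and per-primer resolving power `Rp = Σ_b (1 − 2 |0.5 − q_b|)`.
* **AMOVA** on pairwise band-mismatch distances with the fixation index
  `Φ_ST = σ²_among / (σ²_among + σ²_within)`, permutation p-values, and a
  per-sampling-size fixation-index sweep.
* **Jaccard/UPGMA clustering** with band-bootstrap clade support and
  Newick export.
* **Model-based admixture clustering** of band profiles (Gibbs sampler:
  Dirichlet memberships, per-cluster Bernoulli band frequencies) over a
  grid of cluster numbers K, with Evanno delta-K selection of the
  supported K.
* **A synthetic band-matrix generator** with recorded ground truth
  (four accessions × 60 individuals × 122 bands by default), so the
  whole pipeline runs and is tested without any external data.

See `vignettes/sampling-size-methods.Rmd` for the models, parameter
defaults and design decisions.

## Worked example

```r
library(scotdiv)

g <- generate_band_matrix(seed = 42)   # 4 populations x 60 individuals, 122 bands
m <- g$matrix

r <- subsample_curve(m, "LJ. 1", replicates = 200, seed = 7)
r$per_size[, c("size", "na_mean", "rp_mean", "he_mean", "expected_na")]
#>  size na_mean rp_mean he_mean expected_na
#>     1   47.19   45.22  0.9787       47.18
#>     2   64.11   61.76  0.9826       63.77
#>     3   72.86   69.88  0.9837       72.95
#>     5   83.06   80.04  0.9847       83.25
#>     8   90.83   87.42  0.9853       90.94
#>    10   93.94   90.07  0.9855       93.88
#>    20   99.89   95.89  0.9859       99.99
#>    30  101.81   97.81  0.9860      101.96
#>    40  103.08   99.08  0.9861      102.98
#>    50  103.58   99.58  0.9861      103.60
#>    60  104.00  100.00  0.9861      104.00

plateau_size(r, 90)
#> [1] 10

amova(m)
#>              source  df   SS sigma2 pct_total
#>   among populations   3 1503  8.077     32.93
#>  within populations 236 3882 16.450     67.07
#> Phi_ST = 0.3293
```

Reading the output: this population's full 60-individual sample shows
104 bands; a random sample of 10 individuals already retains 90% of
them on average (`rp_mean`), and the Monte-Carlo mean band counts track
the exact expectation (`expected_na`) closely. Expected heterozygosity
climbs until about ten individuals and then plateaus. The AMOVA
attributes about a third of the band variance to differences among the
four populations (Φ_ST ≈ 0.33).

The same analysis runs end to end with
`run_pipeline(pipeline_config(seed = 1, out_dir = "out"))`, which writes
the retention, diversity, AMOVA, fixation-index, similarity and delta-K
tables as TSV plus the bootstrap-annotated Newick tree, or from a shell
via `inst/scripts/scotdiv-cli.R` (verbs `generate`, `stats`, `rarefy`,
`amova`, `tree`, `structure`, `run-all`).

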