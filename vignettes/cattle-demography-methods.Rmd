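---
title: "Methods: serial-coalescent ABC for cattle mtDNA demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial-coalescent ABC for cattle mtDNA demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The demographic model

`cattleabc` infers the demographic history of domesticated taurine cattle
from mitochondrial D-loop (HVR1) sequences. The model has two demes on the
female line, with all sizes being female effective sizes and time measured
backwards in generations before present (6 years/generation, present fixed
at 2000 CE so that 8,500 BCE is exactly 1,750 generations BP and 6,400 BCE
is 1,400 generations BP):

* **NE (Near East/Anatolia).** Beyond 1,750 generations BP the deme is the
  ancestral wild aurochs population at a constant 45,000. Domestication at
  1,750 generations BP passes the population through a bottleneck of size
  `N_D` (free parameter), after which it grows exponentially to a modern
  size of 1,007,170.
* **EU (Europe).** Founded at 1,400 generations BP by a proportion `P`
  (free) of the NE deme at that time; grows exponentially to a modern size
  of 7,942,392. The NE trajectory itself is not reduced at the split: the
  two demes' trajectories are specified independently, following the
  serial-simulation convention for this model class; this is our stated
  assumption, not asserted of any other implementation.
* **Migration.** Symmetric, per-lineage, per-generation: rate `M_E` (free)
  from the split until 5,000 BCE (kept as the exact rational 7000/6
  generations BP), then `M_L` (free) until the present. No direction is
  distinguished because only a single exchange rate is specified for the
  pair of demes.

The four free parameters carry independent uniform priors:
`N_D ~ U(1, 1000)`, `P ~ U(0, 1)`, `M_E, M_L ~ U(0, 0.01)`.

## Simulation algorithm

The simulator (`simulate_genealogy()`) is a backwards-in-time serial
coalescent: lineages activate at their sampling times (heterochronous
ancient samples), each pair within a deme of current size $N(t)$ coalesces
at instantaneous rate $1/N(t)$ (haploid mtDNA scaling), and each lineage
migrates at the epoch's rate. Exponential-size epochs are integrated by
**closed-form time rescaling**: with $N(s) = A e^{-rs}$ the waiting time
$w$ from $t_0$ solves
$\frac{k(k-1)/2}{Ar}\left(e^{r(t_0+w)} - e^{rt_0}\right) = E$, $E \sim
\mathrm{Exp}(1)$, so no time discretisation error is introduced. Candidate
waiting times for the competing events are drawn per segment between model
breakpoints (sampling times, the migration change, the split, the
domestication time); at the split all European lineages merge into the NE
deme.

Mutations (`add_mutations()`) follow a finite-sites model: hits arrive as a
Poisson process along each branch at rate $\mu L$ per generation, each hit
picks a uniform site and substitutes a uniformly chosen different base, and
the root sequence is uniform random. The rate is 45% per site per million
years, i.e. $\mu = 0.45 \times 10^{-6} \times 6 = 2.7\times10^{-6}$ per
site per generation — the percent-per-million-years figure is interpreted
as a per-site rate, which the magnitude of observed D-loop diversity
supports. No transition bias or
rate heterogeneity is modelled (none is specified for this model class);
the mutation model is intentionally minimal and is cross-validated against
an independent simulator (msprime with JC69) in the test suite.

# Summary statistics and rejection ABC

The observed and simulated datasets are reduced to a 32-element vector
(`abc_stat_vector()`): for each of the four sample groups (ancient NE,
ancient EU, modern NE, modern EU) the five within-group statistics
*K* (haplotype count), *Ĥ* (Nei's unbiased haplotype diversity), *π* (mean
pairwise differences), *S* (segregating sites) and Tajima's *D*; and for
each of the six group pairs the two between-group statistics Φ~ST~ and the
mean cross-group pairwise differences. The exact identity of the original
study's statistics is not published in its main text; this choice is
recorded in every output's metadata and is configurable in spirit — any
alternative set can be assembled from the exported per-statistic functions.
An undefined Tajima's *D* (monomorphic group) is encoded as 0 in the
vector, identically for observed and simulated data, so the encoding
cannot bias the distance ranking.

Rejection (`rejection()`) standardises every statistic by its standard
deviation across the whole simulation table (a MAD option exists),
measures Euclidean distance to the observed vector, and keeps the
`ceiling(tolerance * n)` closest rows, ties broken by row index. No
post-rejection regression adjustment is applied: the inference is plain
rejection — the retained rows themselves are the posterior sample. Posterior
summaries use Gaussian KDE with Silverman's bandwidth and **boundary
reflection** at the prior bounds (512-point grids; 256×256 product kernel
for the joint (N_D, P) density), because several posteriors (notably M_L)
peak at a boundary and unreflected KDE would smear their mass outward.
Credible intervals are highest-posterior-density intervals (smallest
window of the required mass on the KDE grid), not equal-tailed — again
because of boundary-peaked posteriors.

# Descriptive statistics

* **Haplotype calling** (`call_haplotypes()`): under the default
  `wildcard` policy two sequences share a haplotype iff they agree at every
  site where both are non-missing, merged transitively; this keeps every
  nucleotide position in play even when some ancient sequences carry gaps
  or undetermined bases. A `complete_sites` policy (drop columns with any
  missing symbol, then exact identity) is available.
* **π, S**: pairwise deletion of missing sites throughout.
* **Tajima's D** (Tajima 1989 constants) and **Fu's Fs** (Ewens sampling
  formula at θ = π̂, Stirling numbers evaluated in log space so samples of
  many hundreds of sequences are exact). p-values are lower-tail
  proportions from a constant-size neutral coalescent null at θ = π̂
  (10,000 replicates by default); null replicates where the statistic is
  undefined (S = 0 or a single haplotype) are dropped from the
  denominator.
* **Φ~ST~ / F~ST~** (`pairwise_fst()`): the default `phi_st` estimator is
  the two-group AMOVA fixation index with pairwise difference counts as
  squared molecular distances; `haplotype_freq` runs the same variance
  decomposition on 0/1 haplotype-identity distances (a frequency-based
  Reynolds/Weir–Cockerham analogue). Both are exposed because the original
  F~ST~ basis ("Reynolds' genetic distances") is ambiguous between the
  two; the estimator used is always recorded. Permutation p-values shuffle
  individuals between the two groups with sizes preserved and report the
  plain proportion of permutations at or above the observed value.
  Negative estimates are reported as computed and clamped (to 1e-6) only
  when building ordination distances.
* **Mantel test** (`mantel_test()`): Pearson correlation of upper-triangle
  entries, null by jointly permuting rows/columns of one matrix,
  `p = (1 + k)/(1 + n_perm)` so a p-value of zero is impossible.
  Geographic distances are haversine distances (R = 6,371 km) between
  group centroids computed as planar coordinate means — group centres for
  archaeological site clusters and sampling countries are inherently
  approximate, so spherical-mean precision is not warranted.
* **NMDS** (`nmds_embed()`): Kruskal non-metric MDS via MASS::isoMDS (the
  classical toolchain for this plot), 20 random restarts plus a
  classical-scaling start, lowest stress kept, stress reported as a
  fraction.

# The synthetic-data generator

`study_template()` reproduces the study's sampling design: 13 ancient
spatiotemporal groups — Iran/Syria and Western Anatolia in the NE deme
(n = 24 in total), Southeastern Europe, Southeastern Central Europe,
Italy, Southern France, Spain and Central/Western Europe in the EU deme
(n = 169) — plus 100 modern NE and 497 modern EU samples: 790 sequences of
240 bp. Ancient ages are drawn uniformly within each group's period bounds
(only ranges are known per group); each sample then enters the simulator
at its own midpoint age (a group-midpoint rule is available). Site
coordinates are drawn uniformly within coarse per-region bounding boxes.
Group sizes scale with a single factor (floored at 2), giving the "desk"
profile at scale 0.1.

What the generator does **not** emulate: real haplogroup motif structure
(T3/Q/T2/P), sequencing/damage error, non-uniform site rates, and any
geographic population structure within a deme. Passing tests on synthetic
data therefore validate the inference machinery under the model's own
assumptions; they do not show that the model fits real cattle data.

The truth parameters of a generated dataset are written to a separate
sidecar JSON, never to the metadata the pipeline reads.

# Numerical and design choices

* Per-stage and per-row seeds are derived from one master seed by a
  documented integer counter scheme (`derive_seed()`), so batches are
  reproducible independently of execution order and every provenance file
  suffices to reproduce its stage.
* Undefined statistics are `NA` with a `defined` flag at the user surface,
  and 0 inside the ABC statistic vector (see above).
* The simulator refuses EU samples at or beyond the split and P = 0 with
  EU samples (empty founder population).
* The coordinate convention is 1-based inclusive positions on the V00654
  reference; the three standard windows are 434 bp (15,914–16,347 span as
  amplified), 399 bp (15,914–16,312) and 240 bp (16,023–16,262).
* Metadata ages use `age_bce_lo >= age_bce_hi` (lo is the older bound);
  each ancient sample's point age is the midpoint of its range. Whether
  samples should enter at per-sample or group-level ages is not specified
  anywhere; per-sample midpoints are the default, the group rule a switch.

# Problem sizes used by the test suite

The packaged checks run at sizes chosen to give stable Monte-Carlo
verdicts on a single CPU: 20,000 replicates for the pairwise analytic
checks (E[TMRCA] = N, E[π] = 2Nμ, serial-pair branch length 2N + t, each
within 3 Monte-Carlo standard errors), 2,000 replicates for the
neutrality centring of Tajima's D (constant N = 5,000, n = 30, 240 bp — a
θ of about 6.5, typical of D-loop data, where the statistic's small-sample
bias is negligible), 5,000 replicates per side for the
Kolmogorov–Smirnov cross-validation against msprime, and the desk ABC
profile (design scale 0.1, 20,000 simulations, tolerance 1%) for
parameter recovery, with ten pseudo-observed datasets at truth
(N_D = 100, P = 0.7, M_E = 0.002, M_L = 10⁻⁴) sharing one reference
table — the table is the expensive fixed resource, exactly as in real ABC
practice, and the repetitions probe observed-data variability.

# Known limitations

* Desk-scale posteriors are weakly informative: with ~79 sequences and
  20,000 simulations the P and M_E marginals often remain close to their
  priors and the N_D mode has wide repetition-to-repetition spread. The
  full profile (5 million simulations, tolerance 0.1%, full sample sizes)
  is the configuration intended for substantive inference.
* The two-deme model ignores within-Europe structure that the descriptive
  statistics themselves reveal (strong F~ST~ between ancient European
  groups); the ABC estimates are conditional on the model.
* Finite-sites recurrent mutation slightly depresses π and S relative to
  infinite-sites expectations at high θ; analytic checks allow for this.
* NMDS on few groups (e.g. 3) has rotational and reflective degeneracy;
  only distances between embedded points are meaningful.
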