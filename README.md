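# cattleabc

Demographic inference for domesticated taurine cattle from mitochondrial
D-loop (HVR1) sequences. Ancient and modern control-region data carry the
signature of the cattle domestication process: a bottleneck in the Near
East around 8,500 BCE, exponential expansion, the founding of the European
population around 6,400 BCE by a fraction of the Anatolian herds, and
changing gene flow between the two regions. `cattleabc` is for
palaeogeneticists and population geneticists who want to re-run, vary or
stress-test that inference end to end.

The package provides:

* a **serial (heterochronous) coalescent simulator** for a two-deme model:
  ancestral size `N_anc = 45,000`, a domestication bottleneck of size `N_D`
  at 1,750 generations BP, exponential growth to `N_NE = 1,007,170`, a
  European deme founded at 1,400 generations BP by a proportion `P` of the
  Near Eastern deme growing to `N_E = 7,942,392`, and symmetric migration
  at rate `M_E` before and `M_L` after 5,000 BCE (6 years/generation;
  mutation rate 45%/site/Myr on 240 bp). Exponential epochs are integrated
  by closed-form time rescaling; the core is in C++.
* **rejection ABC** over a 32-element summary-statistic vector
  (K, Ĥ, π, S, Tajima's D per group; Φ<sub>ST</sub> and between-group π
  per pair), with uniform priors `N_D ~ U(1, 1000)`, `P ~ U(0, 1)`,
  `M_E, M_L ~ U(0, 0.01)`, reflected-KDE posterior modes and
  highest-posterior-density intervals.
* **descriptive population genetics**: haplotype calling with
  missing-data wildcards, Nei's haplotype diversity, mean pairwise
  differences, segregating sites, Tajima's D and Fu's Fs with
  coalescent-simulation p-values, pairwise Φ<sub>ST</sub>/F<sub>ST</sub>
  matrices with permutation tests, Reynolds' distances.
* **spatial analysis**: Mantel tests of isolation by distance and Kruskal
  non-metric MDS.
* a **synthetic-data generator** reproducing the study design (13 ancient
  spatiotemporal groups plus modern Near Eastern and European samples,
  790 sequences of 240 bp), so the whole pipeline is testable without any
  sequence download.

## Worked example

Generate a pseudo-observed dataset at known parameters, summarise its
diversity, and run a small rejection ABC:

```r
library(cattleabc)

po <- generate_pseudo_observed(
  list(N_D = 100, P = 0.7, M_E = 0.002, M_L = 1e-4),
  study_template(scale = 0.1), seed = 42)

diversity_report(po$aln, po$metadata, by = "abc_group",
                 n_null_sims = 1000, seed = 1)
#>        group  n n_haplotypes     H    pi tajima_D tajima_p
#> 1 ancient_EU 23            3 0.379 0.403   -0.571  0.35781
#> 2 ancient_NE  6            2 0.333 0.333   -0.933  0.46667
#> 3  modern_EU 50           26 0.901 1.932   -2.327  0.00000
#> 4  modern_NE 10            5 0.667 1.800   -1.901  0.00307

scheme <- scheme_from_metadata(po$metadata)
tab <- run_simulation_batch(5000, scheme, mutation_model(), seed = 7)
obs <- abc_stat_vector(split_groups(po$aln, po$metadata, "abc_group"))
post <- rejection(obs, tab, tolerance = 0.01)
s <- posterior_summary(post, n_perm = 1000, seed = 2)
```

This prints `N_D mode 1 (95% HPD 1-279), P mode 1.00, r(N_D,P) = -0.19`
for this seed: the modern groups show the strongly negative Tajima's D of
expanding populations, while a 5,000-simulation desk run yields a wide,
weakly informative `N_D` posterior whose 95% interval still contains the
true value of 100 — at this scale the data constrain the bottleneck only
loosely, which is why substantive runs use millions of simulations
(`default_config("full")`). The slight negative correlation between `N_D`
and `P` among accepted draws reflects their partial confounding: a larger
surviving bottleneck and a smaller founding proportion can produce similar
European diversity.

The full pipeline — synthetic data, Table-1-style diversity report,
F<sub>ST</sub> matrices, simulation table, rejection ABC, Mantel test and
MDS, each stage with a provenance JSON — runs from one configuration:

```r
res <- run_pipeline(default_config("desk", out_dir = "results", seed = 1))
```

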