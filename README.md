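# riverscape

Genetic consequences of habitat fragmentation in dendritic river networks.

Freshwater fish and other obligate stream dwellers disperse only along the
river network, so weirs, dams and other in-stream barriers fragment their
populations in ways that the network's tree shape makes unusually easy to
model — and unusually severe: small, isolated fragments lose genetic
diversity to drift within tens of generations. `riverscape` is an R
toolbox for quantifying that process, written for landscape/riverscape
geneticists working with SNP panels from sites scattered across a river
basin. It covers:

* **Network-aware spatial predictors** — river distance, in-stream barrier
  counts and catchment-membership model matrices derived from an edge-list
  representation of a dendritic network, with sites and barriers placed by
  `(edge, offset)`.
* **StreamTree** — decomposition of pairwise F<sub>ST</sub> into additive,
  non-negative contributions of individual stream sections
  (min<sub>d≥0</sub> ‖y − A d‖², A the pair-by-section incidence matrix),
  locating the reaches that restrict gene flow.
* **MMRR** — multiple matrix regression with randomization: OLS on
  z-transformed unfolded distance matrices, with inference from joint
  row/column permutations of the dependent matrix; plus the conventional
  environmental-predictor chain (VIF filtering, per-category PCA with the
  Kaiser rule, Euclidean distances) and a variance-share summary
  |β<sub>i</sub>|/Σ|β<sub>j</sub>|.
* **Population statistics** — Weir–Cockerham θ (pairwise, global, with
  permutation tests), Weir–Hill population-specific F<sub>ST</sub>,
  unbiased expected heterozygosity, SNP filtering and exact
  Hardy–Weinberg screening.
* **LD effective population size** — Burrows composite r² with a
  P<sub>crit</sub> allele screen, sample-size bias correction, drift
  inversion and parametric confidence intervals, with infinite estimates
  handled explicitly.
* **Fragmentation simulations** — forward-time 1-D stepping-stone
  Wright–Fisher metapopulations (individual-based and allele-frequency
  engines): burn-in to migration–drift equilibrium at m = 0.5, then m = 0,
  tracking the generations needed for global F<sub>ST</sub> to reach 0.2.
* **Synthetic studies** — a generator producing complete, ground-truthed
  riverscape datasets (network + barriers + hierarchically structured
  genotypes + collinear environmental covariates) so the whole pipeline is
  testable without field data.

## Worked example

```r
library(riverscape)

st <- synthetic_study(n_sites = 12, n_catchments = 5, n_barriers = 8,
                      n_loci = 800, seed = 1)
pw <- pairwise_fst_wc(st$genotypes)

fit <- streamtree(st$network, pw$fst)
fit
#> StreamTree additive section-distance fit
#>   66 pairs, 30 sections (12 identifiable)
#>   observed ~ fitted: R^2 = 0.986, beta = 1.000 [0.970, 1.030]
#>   NNLS 1 - SSE/SST = 0.986

f <- mmrr(pw$fst, list(barriers = barrier_count_matrix(st$network),
                       catchment = catchment_model_matrix(st$network)),
          n_perm = 999, seed = 9)
f
#> MMRR: 66 dyads, R^2 = 0.975, model p = 0.001 (999 permutations)
#>           coefficient  ci_lo  ci_hi     p
#> barriers       0.7471 0.7068 0.7874 0.001
#> catchment      0.5609 0.5205 0.6012 0.001
variance_share(f)
#>  barriers catchment
#>        57        43

cfg <- sim_config(ne_total = 500, n_demes = 2, n_replicates = 10, seed = 1)
run_fragmentation(run_burnin(cfg), cfg)
#> fragmentation ensemble: 10 replicates x 300 generations (Ne=500, 2 demes)
#>   mean generations to FST=0.20: 113.1 (10/10 replicates crossed)
```

Reading the output: the StreamTree fit explains 98.6% of the variance in
pairwise F<sub>ST</sub> with non-negative per-section distances (sections
that are co-traversed by every pair, e.g. the two halves of an edge split
by a barrier with no site between, are merged and flagged
non-identifiable). The MMRR coefficients are standardized, so barrier
counts and catchment membership contribute comparably (57% / 43% of the
attributed effect), both significant at p = 0.001 — the minimum possible
with 999 permutations. The simulation says a metapopulation of 500 split
in two by an impassable barrier drifts from F<sub>ST</sub> ≈ 0 to 0.2 in
about 113 generations.

The same steps are scriptable end-to-end on a study directory
(`pipeline_synth()`, `pipeline_all()`), or from a shell via
`inst/cli/riverscape.R` with subcommands
`synth | filter | stats | streamtree | mmrr | ne | simulate | all`.

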