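---
title: "Models and methods behind riverscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riverscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`riverscape` studies how artificial in-stream barriers reshape the genetics
of organisms confined to dendritic (tree-shaped) river networks. This
vignette documents the models the package implements, the assumptions they
make, the tunable parameters and their defaults, and the design choices
taken where more than one reasonable convention exists.

## The river network and its spatial predictors

A dendritic network is represented as an undirected tree: stream sections
(edges with lengths in kilometres), confluences (nodes), sampling sites and
barriers placed on edges by an offset in km from the edge's first node.
Internally the network is re-segmented so that every site and barrier is a
node; paths between sites are then unique section sequences. Three
conventions matter:

* **Sites at edge ends** are snapped to the existing terminal node, so no
  zero-length stub sections arise. Barriers always receive their own node,
  wherever they sit, so they split their edge and can be counted exactly.
* **A barrier at a site's exact position** is placed on the `node_b` side of
  the site; the `node_b` end of an edge is treated as downstream. The
  barrier therefore separates the site from everything beyond it in that
  direction. This is a deterministic tie-break, not a hydrological claim.
* **Barrier counts are undirected.** Nothing in the data distinguishes
  upstream from downstream passability, so a barrier on the path between
  two sites counts once regardless of travel direction.

From this structure the package derives the three spatial predictors of the
analysis: river distance (km along the unique path), barrier count, and the
binary catchment-membership model matrix (0 within, 1 among catchments).
River distances on a tree satisfy the four-point condition; this is used as
a property test.

## StreamTree: additive section distances

The StreamTree model explains each pairwise genetic distance (here,
pairwise Weir–Cockerham $F_{ST}$) as the sum of non-negative contributions
of the stream sections on the path between the two sites:
$y \approx A d$, $d \ge 0$, where $A$ is the pair-by-section incidence
matrix. The package solves the non-negative least-squares problem with an
active-set solver (`pracma::lsqnonneg`). Non-negativity is what makes the
decomposition interpretable: a section's fitted distance is the resistance
it adds, independent of its length.

Identifiability needs care on real networks:

* sections traversed by no site pair carry no information and are reported
  as `NA` (non-identifiable), never as 0;
* sections that are always co-traversed (identical incidence columns — the
  canonical case is the two halves of an edge split by a barrier with no
  site in between) are merged for fitting. Only their summed contribution
  is identifiable; the sum is split equally among the group members and the
  members are flagged `identifiable = FALSE`.

Fit quality is reported two ways: the $R^2$ (and slope with 95% CI) of the
ordinary regression of observed on fitted distances — the conventional
presentation — and $1 - SSE/SST$ of the NNLS solution itself. On exactly
tree-additive input the solver recovers all identifiable sections to
numerical precision; this exact-recovery property is exercised over many
random networks in the test suite.

Fitted section distances are binned for display into the half-open classes
$[0, 0.01)$, $[0.01, 0.05)$, $[0.05, \infty)$; a value on a boundary goes
to the upper bin.

## Population-genetic statistics

**Pairwise and global $F_{ST}$** use the Weir–Cockerham (1984) variance
components with the ratio-of-sums multi-locus estimator: components $a$
(among populations), $b$ (among individuals within populations) and $c$
(within individuals) are summed over loci before the ratio is formed.
Missing genotypes are deleted locus-wise. Negative estimates are reported
as computed — truncation at zero would bias comparisons among weakly
diverged site pairs. Permutation significance shuffles individuals between
the two sites and uses the `(n_perm + 1)` correction, so p-values live in
`[1/(n_perm+1), 1]` and are uniform under the null (tested).

**Population-specific $F_{ST}$** follows the Weir–Hill idea of a
per-population divergence coefficient relative to the pooled total,
computed via allele-matching proportions:
$\beta_i = (M_i - M_B)/(1 - M_B)$ with $M_i$ the unbiased within-site
matching and $M_B$ the mean between-site matching, accumulated over loci as
a ratio of sums. No finite-population small-sample correction is applied
beyond the unbiased matching estimators themselves; on balanced designs the
mean of the $\beta_i$ tracks the global $\theta$ (tested at tolerance
0.02).

**Expected heterozygosity** is the unbiased per-site average of
$2p(1-p) \cdot 2n/(2n-1)$ with $n$ the genotyped individuals at that site
and locus — the allele-count ($2n$) convention. The convention matters at
small $n$ and is kept consistent between documentation, code and tests.

**SNP filtering** retains loci genotyped in at least 70% of all
individuals *and* reaching that call rate in at least 70% of sites, with
global minor allele frequency at least 0.05 (a locus at exactly the
threshold is kept), and optionally one SNP per RAD locus (highest call
rate, first on ties). The Hardy–Weinberg screen runs an exact conditional
test (mid-p, two-sided by probability ordering — the standard enumeration
for SNPs, exact at small $n$) per locus within each site, applies
Benjamini–Hochberg FDR control at 10% within each site, and removes loci
flagged in *strictly more than* half of the sites where they were testable.

## MMRR: attributing differentiation to barriers, hierarchy and environment

Multiple matrix regression with randomization regresses the unfolded
(lower-triangle) dependent distance matrix on unfolded predictor matrices.
All vectors are z-transformed (sample sd), so coefficients are directly
comparable; binary model matrices are z-transformed like the others.
Because dyads are not independent, inference is by randomization: the rows
and columns of the dependent matrix are permuted jointly, t-statistics are
recomputed per permutation, and coefficient p-values count permuted
$|t|$ exceeding the observed with the +1 correction. The model p-value uses
the permuted $R^2$, which is monotone in F because the total sum of squares
is permutation-invariant. Normal-theory 95% CIs are printed for
presentation only and documented as nominal. Only the dependent matrix is
permuted (not residuals); with a single predictor the coefficient equals
the Pearson correlation of the z-transformed vectors, a property the tests
assert to machine precision. Type-I error at $\alpha = 0.05$ under a
simulated null is required to sit in [0.03, 0.07].

Environmental predictors are built in the conventional chain: iterative
VIF filtering at threshold 10 (drop the worst, ties by name; when the OLS
system is under-determined — more variables than sites — the most
correlated pair is pruned first, logged), then per-category PCA on the
correlation matrix keeping components with eigenvalue above 1. When the
Kaiser rule would keep fewer than two components for a category, the
category's raw standardized variables are used instead — a single
anonymous component summarises a category no better than its variables do.
Each retained component or variable becomes a one-dimensional Euclidean
site-by-site distance matrix.

Candidate predictors are screened in univariate MMRR models and combined
in one multivariate model when their coefficient p-value passes the gate
(default 0.05, configurable). The share of explained variation attributed
to each predictor in the multivariate model is
$|\beta_i| / \sum_j |\beta_j| \times 100$, rounded to whole percent. The
attribution rule is a coefficient-ratio convention, not a formal variance
decomposition; it is exact for the package's worked example and is
documented as such.

## LD effective population size

The single-sample estimator uses drift-generated linkage disequilibrium
among physically unlinked loci. Genotypes are unphased, so the package
computes the Burrows *composite* disequilibrium: for a locus pair,
$\hat\Delta$ is half the sample covariance of the 0/1/2 genotype columns
over pairwise-complete individuals. The squared correlation is formed with
the within-locus Hardy–Weinberg disequilibrium terms in the denominator,
$[p(1-p)+D_A][q(1-q)+D_B]$ — i.e. $r^2$ is the squared genotypic
correlation. This form is bounded by 1, equals the textbook
$\hat\Delta^2 / p(1-p)q(1-q)$ under Hardy–Weinberg proportions, and has a
known exact sampling expectation.

Alleles rarer than `pcrit` (default 0.075, the recommended screen for
small samples) are excluded locus-wise before pairing.

Two calibration choices were settled by simulation against a
Wright–Fisher population of known size (the experiment is reproduced in
the acceptance suite):

* **Sampling expectation.** For the squared genotypic correlation the
  expectation under independence is exactly $1/(S-1)$. The widely used
  empirical regressions ($1/S + 3.19/S^2$ above $S = 30$;
  $0.0018 + 0.907/S + 4.44/S^2$ below) were calibrated for a
  differently-normalised composite estimator; applied to this one they
  over-correct and bias $\hat N_e$ upward by tens of percent. The exact
  form is therefore the default, with the regression form available as an
  option.
* **CI degrees of freedom.** The parametric chi-square interval on the
  mean $r^2$ needs an effective number of independent comparisons. Locus
  pairs sharing a locus are strongly dependent: with $L$ loci there are
  $L(L-1)/2$ pairs but far fewer independent ones. Using the raw pair
  count produces markedly anti-conservative intervals (simulated coverage
  near 60%); using $L - 1$ is conservative (simulated coverage near 1) and
  is the default. Jackknife intervals are out of scope.

The drift inversion follows the random-mating relation with its empirical
second-order correction, in the standard two branches around $S = 30$. A
mean $r^2$ at or below the sampling expectation yields $\hat N_e = \infty$
— no drift signal is detectable — and the upper confidence bound is
infinite whenever the lower $r^2$ bound falls below the expectation, which
is the familiar behaviour of such estimates in small samples.

## Fragmentation simulations

The forward-time experiment asks: once barriers cut a stepping-stone
metapopulation into isolated fragments, how many generations does drift
need to raise the global Weir–Cockerham $F_{ST}$ to 0.2 (a level typical of
strongly structured contemporary populations)? A scenario is a total
metapopulation size (100, 500 or 1000) split into 2–10 equal demes on a
1-D chain: burn-in to migration–drift equilibrium at migration rate 0.5
between adjacent demes, then migration set to 0 for 300 generations while
$F_{ST}$ is recorded each generation. Ensembles record the per-replicate
first crossing of the threshold and its mean over replicates; replicates
that never cross are excluded from the mean and counted separately.

Two engines implement the model:

* **Individual engine** — diploid Wright–Fisher with stepping-stone
  migration (interior demes send half their migrants each way, edge demes
  send all to their single neighbour), recombination and mutation over
  four 100-kb genomic elements (mutation $10^{-7}$, recombination
  $10^{-8}$ per bp per generation). The genome is represented by a finite
  set of tracked sites: per-site mutation rates are scaled so the
  genome-wide mutation rate is preserved, recombination between adjacent
  sites follows their physical spacing, and elements recombine freely.
* **Frequency engine** — per-locus allele frequencies with deterministic
  migration mixing and binomial resampling of $2N_d$ alleles per deme. Loci
  (default 2,000, the order of a reduced-representation SNP panel) are
  unlinked and mutation-free; the 20,000-generation mutation-driven burn-in
  is replaced by initialising all demes with identical frequencies drawn
  from a neutral site-frequency spectrum (density $\propto 1/p$) followed
  by a short (default 50-generation) migration–drift settling phase. This
  is justified because burn-in at $m = 0.5$ drives the among-deme
  $F_{ST}$ to ~0 regardless of history, which is exactly the state the
  initialisation creates.

Per-generation $F_{ST}$ is the ratio-of-sums Weir–Cockerham estimator over
all demes, using deme censuses as samples; sites monomorphic in the pooled
metapopulation drop out of both sums automatically. For the frequency
engine, within-deme heterozygosity enters at its Hardy–Weinberg value.

The closed-form pure-drift expectation
$F_{ST}(t) = 1 - (1 - 1/(2N_d))^t$ serves as an independent oracle: the
frequency engine's mean two-deme trajectory must track it within ±0.03 for
150 generations. The two engines agree on burn-in heterozygosity and mean
crossing generation when run under the same model (individual engine with
mutation off and unlinked loci). With its full mutation and linkage, the
individual engine crosses somewhat later and with much more
replicate-to-replicate spread — four linked elements provide few
independent genealogies, and the influx of rare mutations dilutes the
ratio-of-sums estimator — which is consistent with published forward
simulations of this design sitting slightly above the closed-form drift
prediction.

Ensemble runs use the frequency engine by default. Problem sizes in the
test and acceptance suites — 30 replicates per scenario, 2,000 loci, 8–10
replicates for trajectory oracles, reduced burn-ins for the individual
engine — were chosen as the smallest ensembles whose Monte-Carlo error is
comfortably below the tolerances being checked.

## The synthetic-data generator

The generator emulates the structure of a basin-wide riverscape survey:
~25 sites in ~13 catchments on a random binary dendritic tree, 6–18
individuals per site, a few thousand biallelic SNPs, ~15 barriers, and 40
environmental covariates in five categories with planted collinear pairs
(|r| ≈ 0.95) so VIF filtering has real work to do.

Divergence is parameterised at the *branch* level so that StreamTree's
exact-recovery property is exercisable. A per-pair target
$F = \mathrm{base} + a \cdot \mathbb{1}[\text{different catchment}] +
b \cdot \#\text{barriers}$ (defaults 0.03, 0.10, 0.04, truncated to
[0.01, 0.8]) is projected onto the nearest tree-additive set of section
contributions by NNLS on the path incidence matrix (the catchment
indicator is not exactly tree-additive; the projection gap is reported).
Allele frequencies then evolve from a uniform(0.05, 0.95) ancestral state
down the network under the Balding–Nichols model, one Beta step per
section with divergence parameter equal to the section's contribution.
Because a pairwise $F_{ST}$ averages the two root-ward halves of a pair's
path, section contributions are fitted to *twice* the target so realized
divergence sits on the target scale. Genotypes are binomial draws from
site frequencies with 5% missingness by default.

What the generator does *not* emulate: linkage between SNPs, genotyping
error and allele dropout, within-site family structure, selection and
outlier loci, and asymmetric (directional) gene flow. Passing tests
therefore demonstrate that the estimators recover the generating model's
structure, not that real data meet these assumptions. Environmental
covariates are generated independently of the genetic structure, so the
study system has no isolation by environment by construction — the
pipeline is expected to report null environmental effects, and does.

The fixed seed 42 defines the reference ("golden") study used as an
end-to-end regression fixture: its multivariate MMRR must recover positive,
significant barrier and catchment effects, and its per-site expected
heterozygosity must correlate negatively with population-specific
$F_{ST}$ — diversity is lowest where drift has been strongest.

## Numerical conventions and degenerate inputs

* Matrix unfolding uses a fixed canonical pair order; symmetry is checked
  at $10^{-8}$ and constant vectors are rejected by name in the
  z-transform.
* NNLS rank deficiency is handled by column merging, never by silently
  returning one of many solutions for individually non-identifiable
  sections.
* Permutation p-values always use the +1 correction; seeds are explicit
  arguments everywhere randomness occurs, and ensemble replicate seeds are
  derived deterministically from the master seed below $2^{31}$.
* Pairs with undefined $F_{ST}$ (a site with fewer than two individuals)
  are flagged and dropped from fits with a message, not imputed.
* A generation in which all simulated loci are globally fixed carries the
  previous $F_{ST}$ value forward with a warning.

## Known limitations

* The Weir–Hill population-specific estimator is implemented in its
  allele-matching form; other published variants differ by small-sample
  corrections and can shift per-site values slightly.
* MMRR CIs are normal-theory and nominal; only permutation p-values should
  be used for inference.
* The frequency engine omits mutation, so it cannot be used to study
  equilibrium diversity — only differentiation dynamics after
  fragmentation, which is its purpose.
* The variance-share rule is a reporting convention; it does not decompose
  $R^2$ in the commonality-analysis sense.
* Braided (non-tree) networks and directional barrier passability are out
  of scope.
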