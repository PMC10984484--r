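---
title: "Metabolic covariance network analysis with covnet"
author: "covnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance network analysis with covnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covnet)
```

## The analysis

covnet implements group-level *inter-subject covariance network* analysis
for regional FDG-PET data. The input for one group is a table of
standardized uptake value ratios (SUVR): for each animal and each of 27
bilateral brain regions, the regional tracer activity divided by the
cerebellar reference activity (`computeSUVR()`), which removes dose and
body-mass effects. Within a homogeneous group (one genotype, sex and age),
the edge weight between regions $i$ and $j$ is the Pearson correlation of
their SUVR values across the animals of the group:

$$ w_{ij} = \mathrm{cor}\big(\mathrm{SUVR}_{\cdot i},\,
   \mathrm{SUVR}_{\cdot j}\big), \qquad i \ne j, $$

computed after per-region z-scoring (Pearson correlation is affine
invariant, so the z-scoring documents intent rather than changing the
estimate). The result is a symmetric $27 \times 27$ signed weight matrix
with 351 unique edges and a structurally zero diagonal — a group-level
construct, not a per-animal graph. Every downstream quantity (density,
degree, signed strengths, signed clustering, hubs, communities) is a
function of this matrix.

Two permutation procedures attach uncertainty to it:

* **Edge significance (random-shift null).** Each null iterate permutes
  every region's values independently across animals, destroying
  inter-regional covariance while preserving marginals, and recomputes the
  full correlation matrix. Positive and negative empirical correlations
  are handled separately: an edge is compared only against same-sign null
  correlations, and its p-value is the add-one exceedance proportion among
  those. The sign-conditional denominator keeps the test calibrated: with
  the full-permutation denominator the two one-sided tests would jointly
  reject ~10% of null edges at a nominal 0.05, which we verified by
  simulation; the implemented form rejects ~5%. Networks are thresholded
  at p < 0.05 and p < 0.01 (`thresholdNetwork()`), keeping the signed
  weights of surviving edges; stricter thresholds are not offered because
  they tend to fragment the graphs.
* **Edgewise group comparison (label permutation).** For two groups, the
  per-edge statistic is the weight difference $\Delta r_{ij}$; the null
  reassigns the pooled animals to two groups of the original sizes and
  recomputes both networks per iterate. There is no per-animal edge, so a
  literal per-edge t-test does not exist; the difference-of-correlations
  statistic is the only reading consistent with recomputing a null
  network at every permutation. P-values are two-sided with the add-one
  correction, and Benjamini–Hochberg FDR is applied across the 351 edges.

## Signed network measures

Thresholded networks are summarized by density (count and fraction of
surviving edges), nodal degree, and the signed strengths
$s_i^+ = \sum_j \max(w_{ij}, 0)$ and $s_i^- = \sum_j \max(-w_{ij}, 0)$,
both reported as non-negative quantities. The signed clustering
coefficient rescales weights by the network-wide maximum magnitude
($\hat w = w / \max |w|$) and is

$$ C_i = \frac{\sum_{j \ne i} \sum_{k \ne i,j} \hat w_{ij} \hat w_{jk}
   \hat w_{ki}}{\sum_{j \ne i} \sum_{k \ne i,j} |\hat w_{ij} \hat w_{ki}|},
$$

so triangles with an odd number of negative edges count against
clustering; the unit tests pin this formula against an independent
brute-force triangle enumeration at $10^{-12}$. Hubs are the top quartile
of regions — exactly 7 of 27 — by nodal degree or by cumulative absolute
strength $s^+ + s^-$, with ties broken deterministically by region order.
Path-based measures (efficiency, betweenness) are deliberately absent:
their interpretation on covariance networks is unclear.

## Community structure

Community detection maximizes a signed modularity with asymmetric
treatment of positive and negative weights,

$$ Q(\gamma) = \frac{1}{v^+} \sum_{ij} \big(w^+_{ij} - \gamma e^+_{ij}\big)
   \delta_{c_i c_j} - \frac{1}{v^+ + v^-} \sum_{ij}
   \big(w^-_{ij} - \gamma e^-_{ij}\big) \delta_{c_i c_j}, $$

with $e^\pm_{ij} = s^\pm_i s^\pm_j / v^\pm$ — the convention recommended
for correlation-derived networks, where negative within-community weight
is penalized relative to the combined total. `louvainSigned()` is a
multilevel greedy (Louvain) optimizer over this quality with seeded
restarts; on all signed networks of up to 8 nodes it attains the
exhaustive-search optimum in the test suite. Modularity is always
maximized on *unthresholded* networks, which retain the most information.

### Multiresolution consensus (MRCC) and its null model

A single resolution $\gamma$ fixes an arbitrary scale, so `mrcc()` builds
an ensemble across scales and reduces it to a consensus:

1. **Resolution interval.** Bisection locates the interval from the
   coarsest partition the quality function can produce to the finest.
   For correlation networks with negative edges the all-one and
   all-singleton partitions may be unattainable (the negative null term
   changes sign behavior at extreme $\gamma$), in which case the
   community-count plateaus bound the interval; the coarsest regime,
   whose band extends to $\gamma \to 0$, is given one octave of headroom
   below its transition.
2. **Ensemble.** `n_partitions` randomized Louvain runs (improving moves
   sampled with probability proportional to gain, so that only robust
   structure is reproducible across members) are placed by recursive
   geometric bisection of the interval, prioritized by the community-count
   gap between sub-interval endpoints. Every count level and transition is
   represented instead of weighting scales by the arbitrary stretch of the
   $\gamma$ axis they occupy. A log-spaced grid is available as
   `sampling = "grid"`.
3. **Co-assignment.** The fraction of ensemble partitions placing each
   region pair in one community (`coassignment()`).
4. **Hierarchical consensus.** Regions are split recursively. At each
   subset, a split is proposed by Louvain on the co-assignment matrix
   centred at its chance level, refined against the correlations
   (each region moves to the community it correlates with most strongly),
   and then every boundary must pass a *local homogeneous-community
   null*: separating two proposed communities is accepted only if the
   within-minus-between correlation contrast exceeds the $1 - \alpha$
   quantile of the same maximized statistic on data simulated from a
   single equicorrelated Gaussian block fitted to that subset, at the
   group's sample size. Null draws run the same split search and
   refinement, so optimization strength cancels.

The choice of the local null deserves emphasis, because the original
multiresolution consensus literature leaves the variant open and the
obvious candidate fails here. With a dozen animals per group, sample
correlations inside a perfectly homogeneous community spread roughly as
$(1 - \rho^2)/\sqrt{n - 1}$, i.e. by $\pm 0.1$–$0.2$; the strongest noise
pairs then form sub-clusters that persist across the entire resolution
ensemble of the *fixed* dataset. A permutation null on ensemble labels —
which we implemented first, in several variants — treats those
sub-clusters as significant structure, because they are indeed
reproducible in the ensemble; it systematically fragments homogeneous
communities (or, with majority-style guards, arbitrarily under-splits,
depending on how much of the resolution axis happens to lie at coarse
scales). The homogeneous-block null asks the question at the level where
the answer lives — the data: does this subset's correlation structure
exceed what a single equicorrelated community of this size and sample
size produces? The consensus partition is the set of recursion leaves
after a final global refinement; cuts of the recursion tree at increasing
depth form the coarse-to-fine hierarchy.

`ami()` (adjusted mutual information with the permutation-model expected
MI and arithmetic-mean normalization, matching the reference
implementations to machine precision) and `coclassification()` compare
partitions across groups.

## Module-level statistics

`moduleMeanSUVR()` averages SUVR over the regions of one module of a
*single reference partition* for every animal of every group, so the same
regions are averaged everywhere; by convention the reference is the
4-month male WT consensus. `nwayAnova()` fits age, sex and genotype with
all two-way interactions (no three-way term). Group sizes are mildly
unbalanced, so type II sums of squares are the default — order-invariant
for main effects and identical to the classical decomposition when
balanced; type III (with sum contrasts) is available via `ss_type`.
`tukeyKramer()` computes studentized-range adjusted p-values for all level
pairs with the Kramer unequal-$n$ correction, using the full-model
residual mean square and degrees of freedom; which error term fed the
original post hoc grid is not stated, and the full-model residual is the
standard choice.

## The synthetic cohort generator

Real data for this design (2 genotypes x 2 sexes x 3 ages, group sizes
12/11/9, 12/11/10, 11/10/9, 12/12/10) are not bundled; `generateCohort()`
emulates their statistical structure with the minimal model whose truth
every stage can be checked against: each group is i.i.d. multivariate
normal with mean SUVR near 1, marginal SD `noise_sd` (default 0.1, giving
the ~10% inter-animal regional variability typical of such data), and a
planted equicorrelated-block correlation structure — `rho_within` inside
modules, `rho_between` across them, realised by a shared global factor
plus per-module factors, which guarantees positive semidefiniteness for
$0 \le \rho_b \le \rho_w < 1$. Values are clipped below at 0.01 to keep
SUVR positive; at the defaults the clip probability is negligible
(~$10^{-22}$), so seed-stable clipping was preferred over resampling.
Cohort defaults plant 2 modules in WT and 4 in 5XFAD groups (mimicking
the disease-related increase in community count) with
`rho_within = 0.6`, `rho_between = 0.1` — moderate coupling chosen as
realistic for regional tracer covariance; effect sizes are free
parameters of the simulation, not claims about 5XFAD biology. What the
generator does *not* emulate: partial-volume effects, reference-region
bias, litter/microbiome structure, circadian drift, or spatial
autocorrelation of neighbouring regions. Passing tests therefore
demonstrate correctness of the estimators and calibration of the tests
under the generative model, not robustness to those real-data
complications.

## Numerical and design choices

* Sample SD uses the $n - 1$ denominator throughout; Pearson r is
  unaffected.
* The network diagonal is 0, not 1: self-edges carry no information and
  would distort strength sums. Hub metrics always exclude the diagonal.
* Permutation p-values use add-one estimators and can never be 0; the
  smallest attainable value is $1/(n_{perm}+1)$.
* Louvain ties between equal-quality partitions are broken first-found;
  10 seeded restarts for standalone calls, single randomized runs for
  ensemble members.
* The MRCC null critical value is memoized per (subset size, mean
  correlation rounded to 0.02) within one call; 100 Monte-Carlo draws per
  critical value.
* Degenerate inputs: all-zero networks yield a single community with a
  warning; zero-variance regions are hard errors naming the region;
  groups below 3 animals are rejected at construction.
* Every stochastic stage takes an explicit seed; `runPipeline()` derives
  per-stage seeds from one master seed and its reruns are byte-identical.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated data
at sizes chosen to give stable Monte-Carlo estimates in minutes on one
core: calibration of both permutation nulls at 2000 permutations over 20
replicate null cohorts; planted three-module recovery (AMI $\ge$ 0.9
against the planted partition) over 20 seeds with 200-partition
ensembles; oracle equivalence on 50 random signed networks each for
clustering (up to 6 nodes, $10^{-12}$) and Louvain (up to 8 nodes, exact
optimum); and power analyses with 50 replicates. Full-scale settings
(10000 permutations and partitions) remain the `pipelineConfig()`
defaults for real analyses.

## Known limitations

* The MRCC local null assumes Gaussian equicorrelated blocks; heavy tails
  or strong region-size heterogeneity in real data may shift its
  calibration.
* Recovery of a planted boundary fails, correctly, when the sampled data
  do not express it (with $n = 12$, module factors occasionally correlate
  strongly by chance); this is a property of the sample, not the
  estimator.
* At the default cohort's moderate coupling (`rho_within = 0.6`,
  `rho_between = 0.1`) and the study group sizes, the finer 4-module
  5XFAD structure sits at the edge of detectability: the within/between
  contrast of a single module boundary (~0.25–0.4) is comparable to the
  maximized contrast a homogeneous block of that size produces at
  $n \approx 12$, so the consensus typically resolves only the coarser
  levels of the planted hierarchy. Planted-structure recovery is
  validated at the stronger 0.8/0.0 contrast, where the separation is
  unambiguous.
* Edge-level FDR across 351 correlated tests is conservative by
  construction; network-level statistics are the intended inference
  level.
* The pipeline starts from bilateral-averaged 27-region SUVR tables;
  image reconstruction, registration and atlas extraction happen upstream
  of this package.
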