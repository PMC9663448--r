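---
title: "Detecting ecological boundaries in bipartite interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ecological boundaries in bipartite interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the statistical machinery

`netbounds` tests whether regional (ecoregion) and global (biome)
ecological boundaries, and human disturbance gradients, mark abrupt
discontinuities in the composition and architecture of local bipartite
interaction networks — beyond the gradual distance decay of similarity
expected from space and elevation alone, and after controlling for how
differently each network was sampled.

All information enters the models as labelled N × N distance matrices over
the N local networks. Responses are three facets of network dissimilarity;
predictors are boundary membership and environmental, spatial, elevational,
disturbance and sampling distances. The core statistic is a Multiple
Regression on distance Matrices driven by a Generalized Additive Model, so
non-linear distance–dissimilarity relationships are captured by spline
smooths while inference respects the pairwise, non-independent structure of
the data.

## Network dissimilarity responses

For two networks A and B with `a` shared elements, `b` unique to A and `c`
unique to B, the Whittaker/Sørensen-family dissimilarity is
`(b + c) / (2a + b + c)`.

* **Species turnover (β_S)** applies this to the pooled species sets
  (plants and birds together, guild-tagged so equal names across guilds
  cannot collide).
* **Interaction dissimilarity (β_WN)** applies it to the binarized link
  sets of the whole networks. Link weights affect the structure metrics but
  not the beta family; the qualitative treatment of links follows the
  framework that defined these metrics.
* **Rewiring (β_OS)** applies it to the link sets of the two networks
  restricted to shared plants × shared birds. It is undefined — reported as
  `NA` and excluded, never imputed — when the pair shares no plant or no
  bird, or when both subwebs are linkless. `β_ST = β_WN − β_OS` is reported
  for completeness but not modelled. Because β_OS exists only for a subset
  of pairs, it cannot form a full distance matrix; `shared_pairs_subset()`
  exports it as a long pair table with the same covariate distances used by
  the main models.

* **Structural dissimilarity** summarises each network by five weighted
  metrics and takes Euclidean distances between PCA scores of the z-scored
  metric table. The metrics are:
  weighted connectance (Bersier linkage density over species count, with
  base-2 entropy so `2^H` is an effective partner count; base
  configurable); weighted nestedness wNODF; Shannon interaction evenness
  with the `ln(R × C)` denominator ("prod" convention; a single-cell
  network is defined as 0); weighted mean PDI; and Barber modularity Q.

### Numerical conventions worth knowing

* **wNODF.** For each pair of rows, the row with the strictly larger
  marginal total acts as the "upper" row (equivalent to pre-sorting by
  decreasing totals, and what makes the metric invariant to label
  permutation); the pair contributes 100 × the fraction of the lower row's
  positive cells that are strictly smaller than the upper row's cell in the
  same column, and contributes 0 on equal totals or increasing fill.
  Columns are treated symmetrically; the score averages over all row and
  column pairs.
* **PDI.** Flows are padded with zeros to the species' number of potential
  partners in its local web, max-normalised, and averaged as
  `sum(P1 - Pi)/(H - 1)`. The network-level value pools both guilds,
  weighting each species by its total interaction frequency. The
  literature does not pin down the pooling or weighting variable; both are
  explicit arguments (`guilds`) and this default is a package decision.
* **Modularity.** Q is Barber's bipartite modularity on weights. The
  optimiser is a label-propagation search: nodes repeatedly move to the
  module with the largest Q gain (a fresh module is always a candidate;
  ties break to the lowest module index), stable states trigger
  best-positive-gain module merges, and each converged restart is followed
  by three seeded perturbation "kicks" (a third of each guild randomly
  relabelled, then re-optimised) to escape shallow local optima. The search
  restarts from the two canonical unique-label initialisations and from
  ten random initialisations per candidate module count (1 … smaller guild
  size). On random networks up to 6 × 6 the test suite checks the result
  against an exhaustive partition enumeration: Q matches the global
  optimum to 1e-12 on 1000 seeded instances. All randomness is local to a
  seeded generator; the global RNG state is untouched.
* **PCA composites.** Structural and environmental distances z-score their
  columns (constant columns dropped with a warning), run a PCA, and retain
  the smallest number of leading components reaching a variance target
  (default 0.85). Published analyses of this kind often fix dataset-specific
  component counts instead; `n_components` overrides the threshold exactly
  for such replication.
* **PCoA.** Classical scaling by double-centring; negative eigenvalues are
  discarded (no Lingoes/Cailliez correction) and their share of absolute
  inertia is reported. The sampling-methods distance caps its four
  requested axes at the number of positive eigenvalues.
* **Haversine.** Earth radius fixed at the IUGG mean 6371.0088 km.

## The GAM-based MRM

All matrices are aligned on sorted network labels and their lower triangles
vectorized in a fixed pair order. Binary boundary matrices enter the
Gaussian GAM as parametric 0/1 indicators coded 1 = "same region", so a
negative estimate reads "pairs within one region are less dissimilar".
Quantitative matrices enter as thin-plate regression spline smooths
(`k = 10` by default, capped below the number of unique values; terms with
fewer than five unique values fall back to linear with a warning).
Smoothing parameters are estimated by REML.

Significance is by permutation: each iteration draws one permutation of the
network labels, applies it simultaneously to rows and columns of the
*response* matrix only, re-vectorizes and refits, recording |t| for
parametric terms (two-tailed) and F for smooths (upper-tailed, as F is
nonnegative by construction). P-values include the observed statistic,
`p = (1 + #extreme) / (n_perm + 1)`, so 199 permutations bound p below at
0.005 and 1000 at about 0.001. Permuting predictors too would destroy the
very association being tested; permuting the response alone preserves the
within-network dependence structure under the null.

Two refit modes exist; both reuse the preprocessed model structure (the
design matrix never changes under response permutation, only the response
vector does). The default, faithful mode re-estimates the smoothing
parameters by REML on every permutation, keeping the observed and permuted
statistics exchangeable — the property that makes the permutation test
exact. The fast mode (`fast_perm = TRUE`) freezes the smoothing parameters
at their observed-fit values (verified bit-for-bit against direct fixed-sp
refits in the tests). That asymmetry — the observed F benefits from
smoothing adapted to the observed response, the permuted Fs do not — is
anticonservative for smooth terms: in the package's own null calibration
the spatial smooth rejected at 13% instead of 5% under the fast mode,
while the faithful mode stays at the nominal level. Use the fast mode for
exploration and the faithful default for any reported p-value. The
response family is Gaussian on [0, 1] dissimilarities; a beta family would
be a natural extension but is out of scope.

### Deviance partitioning

Unique and shared (Venn) contributions of the variables of interest are
obtained by refitting every reduced model — all subsets of those variables
removed, control terms always retained — with the smoothing parameters of
the surviving smooths frozen at their full-model values, then inverting the
subset-to-deviance map (Möbius/inclusion–exclusion). Freezing matters:
smoothing parameters compensate when a correlated predictor is dropped,
which would contaminate the components. The signed components sum to the
full-model explained deviance attributable to the variables of interest by
construction (the tests assert 1e-6); negative components are retained and
flagged rather than hidden. Components are reported as fractions of total
response deviance. A guard refuses more than five variables of interest
(2^k reduced fits) unless raised explicitly.

### Jackknife by study

`jackknife_by_study()` drops one study at a time, rebuilds every distance
matrix on the remaining networks via a user-supplied recipe (so
study-dependent matrices such as the beta responses are honestly
recomputed), refits without permutations, and tabulates each term's t or F.
Leave-one-out sets with fewer than four networks are flagged as skipped
rather than fitted.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
every step driven by one seeded RNG:

* **Landscape.** Biomes are latitudinal bands (60°S–60°N) split into
  contiguous longitude cells (ecoregions), with sites uniform within cells;
  ecoregions are therefore nested in biomes by construction. Human
  footprint is a low/high mixture independent of region; elevation follows
  a latitudinal gradient plus noise; studies group geographically proximate
  sites (k-means) and carry the sampling covariates and categorical method
  descriptors.
* **Species pools.** Each species has a home ecoregion, an exclusivity
  level derived from the pool-overlap parameters (ecoregion-exclusive,
  biome-exclusive, or cosmopolitan), a range centre near its home
  centroid, a synanthropy class (20% synanthropic), and a latent matching
  trait.
* **Occupancy.** A species occurs at a site with probability
  `p0 · exp(-decay · d) · (1 - boundary_effect)^crossings ·
  disturbance_filter`, where `d` is the distance to its range centre,
  `crossings` counts ecoregion and biome boundaries between the site and
  the species' home, exclusive species never leave their home region, and
  the disturbance filter suppresses sensitive species at high footprint and
  synanthropic species at low footprint.
* **Links.** A fixed global trait-matching web defines which plant–bird
  pairs can interact; realized links among co-occurring species are thinned
  by a detection probability saturating in sampling hours and weighted by
  rounded log-normal draws.

Defaults (3 biomes × 3 ecoregions × 4 sites = 36 networks; pools of 240
plants and 200 birds; overlaps 0.4/0.5; decay 3e-4 per km, a ~3000 km
e-folding consistent with a global landscape; boundary effect 0.3;
disturbance effect 1; sdlog 1; 20–200 sampling hours over 8 studies) were
chosen once so that realized webs resemble published frugivory networks —
typically 5–25 species per guild, passing the >2-species-per-guild
inclusion filter — and produce visible but not overwhelming boundary
signal. Two placement modes exist because geography confounds boundary
membership by construction: the default "confounded" mode is realistic,
while "randomized" shuffles region labels across sites so the boundary term
is orthogonal to space — the mode used for the type-I and recovery
experiments, where identifiability matters.

What the generator does *not* emulate: phenology, migration, taxonomic
error, spatially autocorrelated sampling effort, and abundance-driven
interaction frequencies. Passing the pipeline's tests on synthetic data
therefore demonstrates the statistical machinery is correct and calibrated
under the assumed structure, not that real frugivory data satisfy those
assumptions.

## Validation experiments in the test suite

The suite's deeper checks, with the problem sizes the package runs them at:

* **Oracle equivalence.** β_S/β_WN/β_OS, wNODF, Barber Q and the
  modularity-search optimum agree exactly with naive set-operation,
  per-cell transcription, double-loop and exhaustive-enumeration oracles on
  1000 seeded random networks up to 6 × 6.
* **Type-I calibration.** With a null response (absolute differences of
  i.i.d. site values — exchangeable across networks) on randomized
  30-site landscapes, per-term rejection at α = 0.05 over 200 replicates of
  199 permutations (faithful refit mode) stays within 0.05 ± 0.03, and the
  null p-value distribution passes a KS uniformity check.
* **Parameter recovery.** An additive same-ecoregion shift of −0.07 (pair
  noise sd 0.05, 60 networks) is recovered with the correct sign in every
  one of 100 replicates, mean bias below 0.01, and permutation detection in
  at least 95%.
* **Partition identity.** Venn components sum to the full-model explained
  deviance to 1e-6; independent predictors yield |shared| < 0.01.
* **Analytic geometry.** Haversine quarter/half circumferences and the
  PCoA reconstruction of Euclidean configurations to 1e-8.

## Known limitations

* The Gaussian response on bounded dissimilarities can fit values outside
  [0, 1] near the boundary; estimates remain interpretable as average
  contrasts but a beta-family variant would be more principled.
* The modularity search is a heuristic; its exactness is demonstrated on
  small instances, and on large webs it inherits the usual caveats of
  label propagation (verified only against itself across seeds).
* β_OS is known to be a generous estimate of rewiring; it is used here as
  a detector of shared species interacting differently, not as a
  decomposition of β_WN.
* The faithful permutation mode is O(n_perm) REML fits and is the honest
  default for publication-grade p-values; the fast mode's fixed-smoothing
  approximation is exact only conditional on the observed smoothing
  parameters.
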