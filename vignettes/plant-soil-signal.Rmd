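---
title: "Evolutionary signal in local-scale plant-soil associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary signal in local-scale plant-soil associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosoil)
library(dplyr)
```

## The question

On a fully mapped forest plot with gridded soil chemistry, every species can
be assigned a *soil association*: the median value of a soil variable over
the grid cells its stems occupy. These are "ecological traits" — measured on
the environment, not the organism — and the question phylosoil addresses is
whether closely related species share them: do clades sit on recognisable
positions along soil gradients, and is that structure visible phylogeny-wide
or only at particular nodes?

The package implements the complete analysis chain:

1. **Trait construction** (`species_medians()`): overlay a stem census
   (species, x, y, dbh) on gridded soil layers, extract each stem's cell
   value, and take per-species medians for stems at or above a diameter
   cutoff (default 1 cm, the standard census inclusion rule).
2. **Composite fertility axes** (`transform_variables()`, `run_pca()`,
   `scores_to_grid()`): log-transform the right-skewed extractable
   elements, standardize, run a correlation-matrix PCA over grid cells, and
   turn the leading axis scores into additional grid layers that are then
   treated exactly like soil variables downstream.
3. **Phylogeny-wide signal** (`phylogeny_wide_signal()`, `blomberg_k()`,
   `k_significance()`): mean absolute standardized independent contrast,
   and Blomberg's K, each against a tip-shuffle permutation null.
4. **Node-specific signal** (`node_permutation_test()`,
   `filter_and_flag()`): per-node trait means under two averaging schemes
   against a shared permutation null, with the reporting filters used in
   the community-phylogenetics literature.
5. **Synthetic study systems** (`scenario()`, `make_scenario_bundle()`):
   a generator producing trees, conserved species optima, autocorrelated
   landscapes and clustered, habitat-filtered censuses with known truth,
   so every stage above can be calibrated without access to restricted
   census data.

## The statistics

### Independent contrasts and phylogeny-wide signal

For a trait $X$ on a rooted tree with branch lengths, a post-order pass
computes at each bifurcation with child values $x_1, x_2$ on (adjusted)
branches $b_1, b_2$:

$$C = \frac{x_1 - x_2}{\sqrt{b_1 + b_2}}, \qquad
  \hat x = \frac{x_1/b_1 + x_2/b_2}{1/b_1 + 1/b_2},$$

with the parent branch lengthened by $b_1 b_2 / (b_1 + b_2)$. Under
Brownian motion the $C$ are i.i.d. with variance equal to the Brownian
rate. The phylogeny-wide statistic is the mean of $|C|$ over all internal
nodes; *low* values relative to tip-shuffled nulls indicate conservatism
(related species resemble each other, so standardized differences are
small).

Polytomies are first-class citizens: many community phylogenies are not
fully resolved, and the contrast engine must not silently resolve them. At
a multifurcation the children are ranked by trait value and split at the
median into two groups (ties broken by node id; the lower group takes the
extra child when the count is odd); each group is combined by
$1/b$-weighted means with the harmonic branch combination
$b_g = (\sum 1/b_k)^{-1}$, and a single contrast is taken between the two
groups. This keeps "one contrast per internal node", which is what the
mean-|C| statistic assumes. The rule is isolated in one internal function
so an alternative (e.g. sequential pairwise contrasts) can be swapped, and
every polytomy contrast carries a flag.

### Blomberg's K

With the tip covariance matrix $V$ implied by the tree
($V_{ij}$ = shared root-path length), the phylogenetic mean is
$\hat a = (1'V^{-1}1)^{-1} 1'V^{-1}X$ and

$$K \;=\; \frac{\mathrm{MSE}_0/\mathrm{MSE}}
   {\bigl[\mathrm{tr}(V) - n/(1'V^{-1}1)\bigr]/(n-1)},
  \qquad
  \mathrm{MSE}_0 = \tfrac{(X-\hat a)'(X-\hat a)}{n-1},\;
  \mathrm{MSE} = \tfrac{(X-\hat a)'V^{-1}(X-\hat a)}{n-1}.$$

$K = 1$ under Brownian evolution, exactly 1 on equal-depth star trees for
any data (both ratios reduce to the tip depth), above 1 for
stronger-than-Brownian conservatism. K is invariant to affine trait
transformations and to global rescaling of branch lengths — useful because
barcode-tree branch units are rarely meaningful — and both invariances are
tested. Significance is a two-tailed permutation test: the smaller of the
two add-one tail probabilities of K under tip shuffles, doubled and capped
at 1. Ecological traits are expected to sit *below* 1: a clade tolerating
an extreme end of a gradient clusters there while everyone else spreads
widely, which weakens phylogeny-wide similarity even when node-specific
structure is strong. That asymmetry — little phylogeny-wide signal,
pronounced node signal — is precisely what the node tests are for.

### Node-specific tests

Each internal node gets two observed statistics: the *tip average* (mean
trait over all subtended species) and the *ancestral average* (recursive
equal-weight mean over immediate daughters, so a 100-species subclade
cannot drown out its 2-species sister). Both are compared to nulls from
one shared stream of `R` tip shuffles (default 999); tail p values use
$(r+1)/(R+1)$ with ties counted as extreme, so the smallest attainable p
at $R=999$ is 0.001 and the root's tip average is 1 by construction. A
node is *significant* in a tail only when both averaging methods agree
(configurable), at inclusive threshold $p \le \alpha$ with
$\alpha = 0.05$ per tail by default, uncorrected for multiplicity — the
output records the number of tests so users can correct as they see fit.

Reporting filters (`filter_and_flag()`):

* **Rare-species dependence.** A significant node containing a species
  with fewer than 5 individuals is flagged, and a leave-one-out re-test
  (drop the species, re-prune, re-test with the same permutation count)
  decides its fate: if significance disappears in any re-test the node is
  excluded as *dependent* on a poorly sampled species; otherwise it is
  reported with the flag. Simple exclusion of every flagged node would be
  too blunt — robust clades often contain a legitimately rare member — so
  fragility, not mere presence, is the criterion. A clade reduced to a
  single tip by the removal cannot be re-tested and is conservatively
  treated as dependent.
* **PCA high tail only.** Composite fertility axes are built so that the
  *high* end is the interpretable one; low-tail hits for PCA-axis traits
  are suppressed from reports (but retained in the full results object).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cell_size` | 20 | m | the standard census quadrat scale |
| `min_dbh` | 1 | cm | census inclusion rule, inclusive |
| `R` | 999 | – | permutations; smallest p = 1/(R+1) = 0.001 |
| `alpha` | 0.05 | – | per-tail, inclusive |
| `min_individuals` | 5 | stems | rare-species flag threshold |
| `n_axes` | 3 | – | leading fertility axes carried forward |
| `log_vars` | B, Ca, Cu, Fe, K, Mg, P, Zn, elev | – | right-skewed positive variables; natural log |

Natural log (not log10) is fixed for reproducibility; after
standardization the base is irrelevant to the PCA. Standardization of grid
layers uses the population (1/n) SD — the cells are the whole lattice, not
a sample. PCA is of the correlation matrix (each variable re-scaled to
unit variance), axes are ordered by eigenvalue and oriented so each axis'
largest-|loading| variable loads positively; published loading tables may
differ from yours axis by axis in sign, which is arbitrary.

## The synthetic generator

`scenario()` fixes the study conditions; `make_scenario_bundle()` realises
them:

* **Tree**: pure-birth with `n_species` tips, depth scaled to 1, so a
  Brownian rate of 1 gives roughly unit-variance species optima.
  `collapse_short_branches()` can absorb short internal branches into
  polytomies (lengths pushed into the children, so root-to-tip distances
  are preserved exactly).
* **Optima**: Brownian motion on the tree (rate `sigma2 = 1`), optionally
  with one clade of a chosen size shifted by a stated offset — a planted
  known-positive node for power studies.
* **Landscape**: `n_latent = 3` latent fields of Gaussian-smoothed white
  noise (bandwidth 3 cells) mixed with random weights plus independent
  noise (`noise_sd = 0.6`), each variable affinely rescaled to the target
  mean and range of `default_soil_targets()` — 15 variables with the
  means/ranges typical of a 50-ha lowland moist tropical plot gridded at
  20 m (e.g. extractable aluminum averaging ~1012 mg kg⁻¹ over
  283–1564, phosphorus ~2.9 over 0.3–8.3, pH 4.7, slope 4.3°). Sharing
  latent factors makes the variables cross-correlated, as real soil
  chemistry is; kernel-smoothed noise gives controllable spatial
  autocorrelation without the cost of exact Gaussian-process sampling.
* **Census**: a Thomas-type cluster process per species — 5 parent points
  drawn with cell probability $\propto \exp(-(z - o_s)^2/2\tau^2)$ on the
  standardized driver layer ($\tau = 0.5$ by default; one designated
  driver, default P, so planted signal is interpretable and other
  variables receive signal only through cross-correlation), offspring
  scattered with 30 m Gaussian SD and redrawn if outside the plot.
  Abundances are lognormal with a floor of 5 stems per species;
  diameters are 1 cm plus an exponential deviate calibrated so ~90% of
  stems are below 10 cm. The clustering parameters are stated defaults,
  not estimates for any particular forest.
* **Null variant**: the same landscape, tree and abundances with optima
  shuffled across species — marginals preserved, conservatism destroyed —
  giving the matched negative control used for type-I calibration.

What the generator deliberately does *not* emulate: real spatial
covariance maps, dispersal limitation beyond the parent-offspring kernel,
species' joint responses to several drivers, plant feedbacks on soil.
Passing calibration on these scenarios shows the machinery is correct and
nominally sized under the stated mechanism; it does not certify that tip
shuffling is the right null for strongly aggregated real censuses (a
torus-translation null, out of scope here, addresses that concern at the
species level).

## Numerical choices

* Even-count medians are the mean of the two middle order statistics.
* Cells are half-open $[is, (i+1)s)$; stems exactly on the far plot
  boundary are clamped into the last cell so every in-bounds stem lands in
  exactly one cell.
* Zero-length *terminal* branches are rejected (they make contrast
  standardization divide by zero); zero-length internal branches are
  allowed, flagged, and handled in the limit (infinite weight ⇒ the node
  estimate is the mean of the zero-branch children).
* A singular tip covariance (duplicate root paths) gets a ridge of
  $10^{-8}\,\overline{\mathrm{diag}(V)}$, flagged in the result.
* Permutation tie detection uses a tolerance of $10^{-9}(\max|x| + 1)$:
  a permuted mean that equals the observed one in exact arithmetic can
  differ in the last float bits under summation reorder.
* All permutation streams are seeded and recorded in result objects;
  identical seeds give byte-identical output files.

## Problem sizes used in the shipped checks

The package's calibration checks run at sizes chosen to make sampling
error small relative to the tested bands while staying desk-scale: 1000
random trees (≤ 8 tips) against a brute-force contrast oracle; 200
pure-birth trees of 50 tips for the Brownian calibration of K (mean K
within [0.85, 1.15]); 500 replicates for p-uniformity (KS at α = 0.01);
200 null scenarios of 32 species / 3200 stems for the node-test type-I
band [0.03, 0.07]; 100 replicates of a planted 8-species clade shifted +3
landscape SD at τ = 0.25 among 64 species / 20,000 stems for power
(≥ 80% detection required; observed power is near 100%).

## Known limitations

* The tip-shuffle null ignores spatial autocorrelation of both soils and
  conspecific clumping; with strongly aggregated species its node-level p
  values are anti-conservative in ways the type-I check (which includes
  clumping) only partially probes.
* The polytomy contrast rule is one defensible convention among several;
  results for heavily polytomous trees depend on it (hence the per-node
  flag).
* Ancestral averaging ignores branch lengths by construction; it is a
  clade-size correction, not an ancestral-state estimate.
* `filter_and_flag()` re-tests with the same seed and R; at very small R
  the leave-one-out verdict inherits Monte-Carlo noise.
* K on median-based ecological traits is diluted by sampling noise in the
  medians of rare species; expect K well below 1 even for strongly
  conserved optima, with significance carried by the permutation test.
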