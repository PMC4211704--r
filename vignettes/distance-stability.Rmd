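---
title: "Distance dependence and the stability of functional connectivity change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance dependence and the stability of functional connectivity change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connstab)
```

## The question

Within a single task condition, functional connectivity between two
brain regions — the Fisher-z-transformed Pearson correlation of their
activity time series — decays with the Euclidean distance between the
regions' centroids: nearby regions are more strongly coupled. Whether
*changes* in connectivity across tasks or groups also depend on
distance is a different question with two competing answers: either
short-range connections are more stable (proximal cortex shares
function, so local coupling should resist task demands), or changes are
distance-blind (a network balancing local segregation against global
integration should be free to reconfigure any edge). A third, sharper
regularity concerns homotopic edges — those joining a region to its
mirror-image partner in the opposite hemisphere — which are both
unusually strong and, plausibly, unusually stable.

`connstab` implements the analysis chain needed to distinguish these
hypotheses and, just as importantly, a synthetic-data generator in
which each hypothesis can be *planted*, so that every stage of the
chain has a parameter-recovery test rather than only face validity.

## The analysis chain

**Connectomes.** Each subject's condition-specific `T x n` ROI time
series becomes an `n x n` Pearson correlation matrix, Fisher
transformed (`z = atanh(r)`, `|r|` clamped at `1 - 1e-7`, diagonal set
to 0). All edge-level work uses one canonical vectorization of the
`n(n-1)/2` unique edges (row-major upper triangle), shared by every
module.

**Task PLS.** The group-by-condition structure is summarized by a
cells-by-edges matrix of cell means, column-centered by the grand mean
across cells. Its SVD is the mean-centered form of task partial least
squares: each latent variable (LV) pairs a design salience vector (a
contrast over cells) with a unit-norm edge salience vector, and
`d_k^2 / sum(d^2)` is the fraction of cross-block covariance explained.
Centering the cell means is equivalent — up to a constant column
scaling when cells are balanced — to the SVD of the cross-block
covariance between the edge data and a dummy-coded, centered design
matrix; the test suite asserts this equivalence on random instances
rather than assuming it.

LV significance uses 500 permutations: whole subjects are relabeled
across groups and condition labels are shuffled within subject (both
applied, because the model targets group-by-condition interactions; a
conditions-only mode is available via `mode = "conditions"`). The
p-value of LV *k* is the raw proportion of permuted *k*-th singular
values at or above the observed one — position-wise comparison, no +1
smoothing. Edge reliability uses 500 bootstrap resamples of subjects
within group (condition labels preserved); each resample's saliences
are aligned to the original fit by an orthogonal Procrustes rotation
computed on the design side, so axis reflections between resamples do
not masquerade as sampling variance. The bootstrap ratio (BSR) is
salience divided by the bootstrap standard deviation, with standard
errors below `1e-12` floored and flagged rather than divided by.

**Change maps and the independent-pairs null.** Edge-level change is
quantified three ways — LV1 saliences, bootstrap ratios, and the
difference of two conditions' group-averaged z matrices (the two cells
with extreme LV1 design saliences, unless overridden) — plus the
absolute-value versions of the salience and difference maps, which run
through identical code paths. The all-edges correlation between change
and distance is reported, but explicitly labeled descriptive: edges
sharing a node are not independent observations (knowing `r(a,b)` and
`r(a,c)` constrains `r(b,c)`), so its nominal p-value would be
anticonservative. Inference instead uses the independent-pairs null:
each of 1000 resamples draws a uniform random perfect matching of the
nodes (Fisher–Yates shuffle, consecutive pairing, one node dropped when
`n` is odd), giving `floor(n/2)` edges that share no node, and
correlates distance with change over just those edges. The sampling
distribution of these coefficients yields `mean_rho`, its spread `se`,
and one-tailed `p_greater`/`p_less` (exact zeros split half-and-half so
the two always sum to 1). Spearman is the default coefficient, with
Pearson selectable. Two further diagnostics guard against structure
hiding in the dense cloud: a 2-D density histogram, and a PCA outlier
check that flags the 5% most positive and most negative orthogonal
displacements from the principal axis of the standardized
(distance, change) cloud and reports the correlation inside the
flagged set.

**Stratification.** The grand-averaged connectome (negative weights
zeroed) is partitioned by the Louvain algorithm, best of 100 seeded
runs by modularity Q; edges are classified within/between module,
intra/inter hemisphere, and homotopic/non-homotopic, and the
distance–change analyses re-run per stratum with the matching
restricted to pairs whose edge lies in the stratum (samples retaining
fewer than 10 eligible pairs are redrawn; strata under 10 edges are
reported as skipped). Finally, the homotopic-stability test pools all
inter-hemispheric change values, takes the empirical 2.5th/97.5th
percentiles as a 95% interval, and compares the proportion of
homotopic versus non-homotopic values falling outside it.

## The generator and what it does (not) emulate

`make_parcellation()` places `n_pairs` left-hemisphere centroids
uniformly in a box of side `extent` (default 140 mm, a brain-scale
extent) and mirrors them in the `x = 0` plane, plus optional midline
nodes. `make_ground_truth()` fixes the population structure:

| parameter | default | meaning |
|---|---|---|
| `r0` | 0.5 | baseline correlation at zero distance |
| `decay_length` | 50 mm | e-folding length of `r0 * exp(-d / decay_length)` |
| `homotopic_boost` | 0.15 | additive correlation increment on homotopic edges |
| `effect_size` | 0.1 | scale (Fisher-z units) of the condition effect |
| `effect_profile` | `"flat"` | effect magnitude vs distance: flat / increasing / decreasing |
| `homotopic_stability` | 0 | effect multiplier on homotopic edges (0 = perfectly stable) |

Defaults encode the distance-decaying baseline and the
stable-homotopic-edges regime; `effect_profile` is the one knob that
switches between the null being tested (`"flat"`: effect magnitudes
drawn i.i.d. of distance) and a positive control (`"increasing"`:
effect proportional to the distance z-score). Correlations are capped
at 0.95 before use, keeping Fisher z finite without hugging ±1.
Condition `k` of `K` applies the effect with a centered weight running
evenly from −0.5 to +0.5; the effect is added in Fisher-z space
(`r = tanh(atanh(r) + w * effect)`), which makes effect sizes exact in
z units and keeps `|r| < 1` automatically. The assembled matrix is
symmetrized, unit-diagonal, and repaired to the nearest positive
semi-definite correlation matrix by eigenvalue clipping at zero
followed by diagonal renormalization (a congruence, so semi-definiteness
survives); matrices with minimum eigenvalue above `-1e-8` are accepted
unrepaired. Note that when repair does fire it perturbs *all* entries
slightly, including homotopic ones — exact condition-invariance of
homotopic edges holds for parameter settings where the constructed
matrix is already PSD. Subject time series are independent draws from a
zero-mean multivariate normal with the cell's population covariance;
one RNG stream per dataset, every stochastic operation takes an
explicit seed, and a fixed seed reproduces a dataset byte for byte.

The generator deliberately omits BOLD hemodynamics, temporal
autocorrelation, motion artifacts and realistic atlas geometry. Passing
tests therefore demonstrate that the *statistics* behave as claimed —
calibration under the flat null, power against planted
distance-dependence, recovery of planted homotopic stability — not that
any particular empirical dataset satisfies the generative assumptions.

```{r generator}
p <- make_parcellation(n_pairs = 15, seed = 2)
truth <- make_ground_truth(p, n_conditions = 2, effect_profile = "flat",
                           seed = 3)
dat <- sample_dataset(p, truth, n_subjects_per_group = 8,
                      n_timepoints = 100, seed = 4)
ds <- connectivity_dataset(dat)
distance_fc_by_cell(ds)
```

## Numerical and design choices

* **Sign convention.** Each LV's design salience vector is flipped so
  its largest-magnitude entry is non-negative; edge saliences flip with
  it. Consequently the sign of a recovered salience pattern relative to
  a planted effect is not identifiable, and recovery is assessed as
  `|cor|`.
* **Tie and degenerate-input rules.** Exactly-zero resampled
  coefficients split evenly between `p_greater` and `p_less`. Samples
  with zero variance in either member of a matched pair set are redrawn
  (at most 100 attempts). All-zero weight matrices partition to a
  single flagged module with Q = 0. Collinear (distance, change) clouds
  report zero displacements, tie-broken flagging by index order, and a
  degenerate within-outlier correlation. Degenerate bootstrap data
  (identical subjects) yields exact zero standard errors — the variance
  accumulates via Welford's online algorithm specifically so this case
  is exact — and every edge is flagged instead of ratioed.
* **Which matrix is partitioned.** Louvain runs on the z matrix
  averaged over all groups, conditions and subjects; per-cell matrices
  can be passed explicitly. Resolution is fixed at `gamma = 1`.
* **Within-condition summaries** are computed on group-averaged z
  matrices (a per-subject mode is available through
  `distance_fc_correlation()` directly). Pearson is the default for the
  within-condition decay summary; the independent-pairs inference
  defaults to Spearman, the coefficient conventionally written as rho.
  No thresholding of negative correlations is applied anywhere.
* **Seeds.** A single master seed spawns per-stage seeds
  deterministically; `run_pipeline()` is reproducible end to end,
  including Louvain and all resampling.

## Problem sizes used in the shipped checks

The package's statistical validation runs on generator output at 60
nodes (30 mirror pairs), 20 subjects, 2 conditions and 200 time points
— 1770 unique edges — with 1000 independent-pairs samples, and 50
replicate datasets for the calibration and recovery properties. The
permutation-test false-positive rate is checked over 200 replicate
null datasets at a reduced size (30 nodes, 10 subjects, 60 time
points), since exchangeability calibration is a property of the
permutation scheme, not of problem size. These sizes are the package's
own validation choices; all of them are plain function arguments and
scale up freely.

## Limitations

Euclidean distance is a proxy — it ignores cortical folding and true
fiber lengths, and no geodesic alternative is offered. The PLS
implementation is mean-centered task PLS with two blocks; behavioral
PLS and split-half stability are out of scope. The independent-pairs
test is deliberately conservative: each resample uses only
`floor(n/2)` of the `n(n-1)/2` edges, so weak global trends that an
(invalid) all-edges test would flag can go undetected — that is the
price of honest independence. The MAT-v5 reader covers the subset of
the format used by connectivity archives (numeric, cell, struct and
character arrays, zlib-compressed elements, little-endian); sparse
arrays and HDF5-based v7.3 files are not supported.
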