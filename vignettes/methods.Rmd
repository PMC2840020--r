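---
title: "Models and methods behind swampcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind swampcat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

swampcat re-implements, as a tested and reusable pipeline, a species
distribution analysis for the flat-headed cat: a presence/background
maximum-entropy niche model, omission-threshold range maps, habitat-class
reclassification, buffer-zone contingency analysis with an
autocorrelation-adjusted G test, a habitat suitability index, and
habitat-loss and protection accounting. This vignette explains the models,
the parameters that matter, the numerical choices, and what the synthetic
landscapes that the test suite runs on do and do not show about real data.

## Spatial data model

All rasters live on a planar grid in kilometre units with square pixels
(`grid_spec()`), the top-left corner as origin, and cell `(i, j)` centred at
`(origin_x + (j - 0.5)·res, origin_y − (i - 0.5)·res)`. There is no
geographic CRS handling: the latitude/longitude workflow of a real GIS
analysis is emulated on a flat grid, which removes projection ambiguity at
the ~1 km working resolution where the two are practically equivalent.
Nodata cells are `NA` and every statistic ignores them. Rasters are stored
as plain-text ESRI ASCII grids, which round-trip bit-exactly and keep the
package free of binary artefacts.

Distance to water is the exact Euclidean distance (km) between cell centres,
computed with `EBImage::distmap()` from a rasterized water mask (the real
analysis measured distances to vector river features; at 1 km resolution the
two are equivalent, and the transform is tested against a brute-force
minimum on every grid up to 30 × 30).

## The maximum-entropy model

The model is a Gibbs distribution over landscape cells,
`q(x) ∝ exp(Σ_j λ_j f_j(x))`, normalized over a background sample (default
10,000 cells drawn without replacement). Fitting maximizes the penalized
presence log-likelihood

```
mean_presence η(x) − log Σ_background e^{η(x)} − Σ_j β_j |λ_j| .
```

Choices and their rationale:

* **Features.** Each predictor is min–max scaled on the background and
  clamped to `[0, 1]` at prediction time. "Auto" feature selection uses
  linear + quadratic terms below 15 training presences and adds forward
  hinge features (8 equally spaced knots per predictor) from 15 presences
  on; products are available but off by default. This mirrors common maxent
  practice; the original software's exact per-sample-size rules are not
  documented well enough to copy, and the setting is fully configurable.
* **Penalty.** `β_j = multiplier · sd(f_j on presences)/√m`, with
  regularization multiplier 1 by default. This is a simple, documented rule
  that is monotone in the multiplier (the test suite checks that raising the
  multiplier never activates more features); the original software's tuned
  per-feature-class tables are deliberately not reproduced.
* **Optimizer.** Monotone proximal-gradient ascent: a soft-thresholding step
  on the L1 part, an adaptive step size that grows after accepted steps and
  halves until the objective does not decrease. What is normative is the
  contract — the objective trace is non-decreasing, iteration stops when the
  improvement falls below the convergence threshold (default 1e-4) or at the
  iteration cap (default 1000) — not the particular algorithm.
* **Logistic output.** `e^H q/(1 + e^H q)`, where `H` is the entropy of the
  fitted raw distribution over the background. Under a signal-free model the
  raw distribution is uniform, `q = 1/B`, `H = log B`, and every cell scores
  exactly 0.5; this anchors the interpretation of the logistic scale.
* **Replicates.** The ensemble (default k = 10) refits on random 75/25
  presence splits against one shared background, reports train/test AUC per
  replicate, and averages the logistic surfaces. AUC is the rank-based
  presence-versus-background statistic (ties count one half), so it is
  invariant under monotone transforms of the scores.
* **Variable contribution** is permutation importance: the drop in
  presence-versus-background AUC when one predictor's values are permuted
  across the evaluation cells, averaged over permutations (default 3),
  floored at zero and normalized to 100%. The original software's
  path-dependent "percent contribution" heuristic is not reproduced, so
  contributions are comparable in ranking but not numerically.
* **Environmental distance baseline.** One minus the rescaled minimum
  Euclidean distance, in background-standardized predictor space, to any
  presence. It serves as an independent sanity check on the maxent surface
  (their correlation at 5,000 sampled cells is part of the test suite).

**Omission thresholds.** To binarize the mean surface, the occurrence scores
(training and test records pooled) are sorted ascending and the threshold is
the score at 0-based index `floor(ω·N)` for omission fraction ω ∈
{0, 0.1, 0.2, 0.3, 0.4}; ties at the threshold count as suitable. This
guarantees the strictly-omitted fraction never exceeds ω. Thresholds are
computed on the ensemble-mean surface (computing them per replicate would
be equally defensible; the mean surface is what the downstream maps use).

## Habitat classes, buffers, and the adjusted G test

Land-cover products are reclassified to ordinal classes 0 (unsuitable) to 4
(very good: flooded/peat-swamp forest, mangrove) with built-in mappings for
GlobCover, GLC2000 and SarVision. Unmapped codes are an error by default
(`assign_class_0` is available). Human population density maps to the same
scale: class 0 above 25 inhabitants/km², then 10–25, 5–10, 1–5, and class 4
below 1. The published class intervals overlap at their endpoints; we assign
shared endpoints to the lower-suitability class (10 and 25 → class 1, 5 →
class 2, 1 → class 3) and treat densities below 1 as effectively uninhabited
(class 4). This boundary resolution is a package decision — the source
intervals do not determine it.

Buffers around records are circles of 12 km² — three times a 4 km² home
range, itself the rounded arithmetic mean of four published home ranges of
the leopard cat, a closely related surrogate (1.75, 2.1, 5.8, 7.5 km²; mean
4.29, rounded to 4). The buffer shape and inclusion rule are not documented
in the source analysis; a circle with centre-in-circle pixel inclusion is
the common zonal-statistics behaviour and reproduces the reported mean of
roughly 11.5 pixels per 12 km² buffer. The pixel containing the record is
always included, and masked pixels are excluded from counts and totals.

Per-epoch pooled counts form a 2 × 5 table tested with the log-likelihood
statistic `G = 2 Σ O ln(O/E)` (`0·ln 0 ≡ 0`; all-zero columns dropped before
`df = (r−1)(k−1)`). Because pixels within one buffer are spatially
dependent, G is deflated by `1 + λ` with λ computed from the mean number of
pixels per buffer `n` — `(√n − 1)/2` for the order-number indicator,
`√n − 1` for the distance-class indicator — or, at the extreme, divided by
`n` itself. `n` is a mean and is used at full (non-integer) precision; the
shipped table of published G summaries reproduces all printed adjusted G
values at three decimals only under full precision, which also resolves a
one-unit rounding inconsistency in one printed correction factor. The
adjusted statistic is referred to chi-square with the original degrees of
freedom. A simulation in the test suite checks the motivating behaviour
directly: with block-duplicated (autocorrelated) buffer pixels the
unadjusted test over-rejects under the null while the order-indicator
adjustment brings the rejection rate down at or below it.

## HSI and accounting

`HSI = (M²·L²·H)^{1/5}` with classes rescaled to weights
{0, 0.25, 0.5, 0.75, 1}. The index is zero whenever any component is zero,
monotone non-decreasing in each argument, and bounded by 1 (both properties
are tested on a lattice). Key localities are connected components of cells
with HSI at or above a threshold, labelled under 8-connectivity — diagonal
adjacency counts, so river-following corridors are not split — and filtered
by a minimum area. The threshold and minimum area have **no defensible
default from the source analysis**, which identified localities visually;
both are required parameters of `key_localities()` and deliberately carry no
claimed provenance (the pipeline default of 0.5 / 25 km² is only a starting
point for exploration).

Habitat loss within a range mask is the share of unmasked pixels in classes
0–2; potential habitat is the conjunction suitable ∧ land-cover class ∈
{3, 4} ∧ population class ∈ {3, 4}; protection is the protected share of
potential habitat, compared against the protected share of all class-3/4
cells. The accounting sweep emits one row per (scheme, omission fraction).

## The synthetic landscape generator

`generate_landscape()` emulates the real input bundle on a 200 × 200 km grid
at 1 km resolution by default: altitude as a smoothed Gaussian random field
(smoothing radius 8 px); 19 climate-like layers as random fields partially
correlated with altitude, one of them a driest-month precipitation analogue
(mildly anti-correlated with altitude); rivers as descending noisy walks
from high-altitude cells; land-cover classes drawn per cell with the good
classes increasingly likely at high true suitability; population density as
log-normal decay around hotspots placed in the low-altitude 40% of cells
(settlements concentrate in lowlands); and a protected mask covering 23% of
cells, strongly biased toward high altitude (reserves in this region sit
squarely in the uplands, away from the well-watered lowlands the species
needs).

True suitability is logistic in distance to water (dominant and strictly
decreasing, −0.8 per km), driest-month precipitation (+0.6 per SD) and
altitude (−1.0 per SD, reflecting how strongly lowland-restricted the
species is). Records are drawn by rejection sampling proportional to
(logit-jittered, SD 0.5) suitability, jittered within their cell, and
greedily thinned at 1 km, with defaults of 29 historical + 59 recent = 88
records. Both epochs sample one landscape; the historical/recent contrast is
created afterwards by `degrade_landcover()`, which converts class-3/4 cells
inside historical-record buffers to classes 0–2 with probability 0.6 (a
quarter of that in recent buffers). The degradation strength of 0.6 is the
generator's default study condition: strong conversion around long-known
sites, mild conversion around recent ones.

What passing tests on these landscapes show — and what they do not: the
pipeline recovers planted structure (distance-to-water ranked first, high
test AUC, a significant epoch contrast, protection concentrated outside
potential habitat), so the machinery is sound end to end. They do **not**
validate the realism of any particular real-world prediction: the climate
fields have no bioclim marginal distributions, the river networks are not
hydrologically realistic, record dates and the 25-year epoch cutoff are not
modelled, and positional error in record coordinates is absent.

## Problem sizes and numerical notes

The test suite runs the recovery checks at the generator's default 200 × 200
grid with 10-replicate ensembles over 20 seeds, the correlation check on
5,000 sampled cells, the type-I-error simulation at 500 replicates, the
epoch-contrast power check at 12 seeds, and all oracle identities on grids
of at most 30 × 30 — sizes chosen so the whole suite completes in a few
minutes on one CPU while keeping every Monte-Carlo margin wide.

Degenerate inputs are handled explicitly: empty water masks, all-constant
predictor stacks, zero-variance correlation samples, empty habitat or range
masks, epochs without buffers and contingency rows with zero sums are
errors with messages; constant predictors are dropped from feature sets with
a warning; buffers fully outside the grid or fully masked yield empty/zero
summaries with a warning. Ties are resolved as documented: at the omission
threshold, upward (`≥` is suitable); at class-interval endpoints, toward the
lower-suitability class; in patch labelling, by raster scan order.
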