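# swampcat

Presence-background niche modelling and habitat accounting for the
flat-headed cat (*Prionailurus planiceps*), a lowland wetland felid of
Sundaland — and, more generally, for any species whose occurrence data are a
small set of presence-only records scattered over decades.

The package provides, as one tested pipeline:

* a **maximum-entropy presence/background model** with replicate ensembles,
  rank-based AUC evaluation, permutation variable contributions and an
  environmental-distance baseline;
* **omission-threshold range maps** (0–40% of records allowed below the
  suitability cutoff);
* **land-cover and human-population reclassification** into the ordinal
  habitat classes 0–4 (built-in mappings for GlobCover, GLC2000 and the
  SarVision Borneo classification);
* **buffer-zone contingency analysis**: class tallies in 12 km² circular
  buffers around records, pooled into a historical × recent table;
* a **log-likelihood G test with spatial-autocorrelation correction**;
* a **habitat suitability index** and habitat-loss / protected-area
  accounting;
* a seeded **synthetic landscape generator**, so the entire pipeline runs
  and is tested without any external raster downloads.

## The statistics at the core

**Maxent.** With features `f_j(x)` (min–max scaled per predictor on the
background sample, expanded to linear, quadratic and hinge terms), the model
is the Gibbs distribution `q(x) ∝ exp(Σ_j λ_j f_j(x))` over the background,
fitted by maximizing the L1-penalized presence log-likelihood

    mean_presence η(x) − log Σ_background e^{η(x)} − Σ_j β_j |λ_j|,

with `β_j = multiplier · sd(f_j on presences)/√m`. Logistic output is
`e^H q / (1 + e^H q)` where `H` is the entropy of the fitted raw
distribution, so a typical background cell scores near 0.5 when there is no
signal.

**Adjusted G.** Buffer pixels are spatially dependent, so the pooled 2 × k
log-likelihood statistic `G = 2 Σ O ln(O/E)` overstates the evidence. G is
deflated by a factor `1 + λ`, with `λ` from the mean pixels per buffer `n`:
`(√n − 1)/2` (order-number indicator), `√n − 1` (distance-class indicator),
or — most conservatively — the factor is `n` itself, every buffer collapsing
to one observation. The adjusted G is referred to chi-square with the
original degrees of freedom.

**HSI.** Per pixel, `HSI = (M² · L² · H)^{1/5}`: the geometric mean of model
probability `M`, rescaled land-cover weight `L` and rescaled population
weight `H` (classes 4…0 map to 1, 0.75, 0.5, 0.25, 0), with double weight on
`M` and `L`. Any unsuitable component zeroes the index.

## Worked example

```r
library(swampcat)

# a seeded 200 x 200 km synthetic study area with 29 historical + 59 recent
# records and land-cover degradation concentrated around historical sites
study <- simulate_study(landscape_config(seed = 1))

tab <- epoch_contingency(summarize_buffers(study$landcover, study$records))
tab
#> <epoch_contingency> 88 buffers, 11.943 pixels/buffer
#>            class_0 class_1 class_2 class_3 class_4
#> historical     106      85      90      29      32
#> recent         167     129     143     177      93

adjusted_g_tests(tab)
#>   indicator     G n_pixels lambda factor  G_adj df         p
#> 1     order 53.36    11.94  1.228  2.228 23.949  4 8.179e-05
#> 2  distance 53.36    11.94  2.456  3.456 15.439  4 3.872e-03
#> 3   extreme 53.36    11.94 10.943 11.943  4.468  4 3.464e-01
```

The buffers around historical records are visibly shifted toward the poor
classes 0–2; the epoch contrast stays significant under both geometric
autocorrelation corrections and, as expected, loses significance only under
the extreme correction that treats each 12-pixel buffer as a single
observation.

```r
ens <- fit_ensemble(study$landscape$stack, study$records, seed = 2)
glance(ens)
#>    k n_presence n_background mean_auc_train mean_auc_test
#> 1 10         88        10000          0.987         0.982

head(variable_contribution(ens, seed = 3), 3)
#>    predictor auc_drop contribution
#> 1 dist_water  0.41620        94.51
#> 2    clim_01  0.00841         1.91
#> 3   altitude  0.00819         1.86
```

The ten-replicate ensemble discriminates presences from background almost
perfectly (mean test AUC 0.982) and correctly identifies distance to water —
the variable that drives the generator's true suitability — as the dominant
predictor.

The full pipeline (fit → thresholds → reclassification → buffers → G tests →
HSI → accounting, with a hash manifest for reproducibility) runs from a
single configuration:

```r
run_pipeline(pipeline_config(seed = 1), "outputs")
```

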