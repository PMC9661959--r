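---
title: "A systems framework for mapping tree-restoration outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A systems framework for mapping tree-restoration outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`restoscape` evaluates a concrete restoration intervention — planting
riparian forest buffers of fixed width along river centrelines in a mixed
forest–agricultural landscape — before any tree is planted, by propagating
the changed landscape configuration through three statistical pathways:

1. **Microclimate and crops.** Ground and leaf surface temperature, leaf
   fluorescence and crop yield are modelled as functions of vegetation
   canopy closure, each as both a Gaussian GLM and a regression-spline
   smooth; the simpler model is kept unless a nested F-test rejects it at
   `alpha = 0.05`.
2. **Biodiversity.** Per-taxon richness classes (low/medium/high species
   counts), threatened-species presence, and plant/seed-eating guild
   richness are modelled by linear discriminant analysis (LDA) on a stack
   of landscape-configuration covariates, after a Pearson collinearity
   filter (|r| < 0.7) and greedy forward selection on Wilks' Lambda gated
   by a partial-F test. Fitted models predict per-pixel class probabilities
   for the baseline and the scenario covariate stacks.
3. **Human–wildlife conflict and wellbeing.** Crop-raiding (elephant)
   presence/absence events are modelled by the same selection + LDA
   pipeline, giving a per-pixel risk surface; household wellbeing is a
   composite index over 20 indicators in five equally weighted dimensions,
   linked to damage/gender through village random-intercept linear models
   and to the ordinal perception-of-nature score (0–4) through
   proportional-odds regression with village fixed effects.

Baseline-vs-scenario changes are reported as delta rasters, a categorical
high-risk change mask (risk strictly above 0.5 before/after), and mean
changes aggregated over plots, habitats and crop-production systems.

## The spatial substrate

All rasters share one planar grid at 30 m resolution (the working
resolution of the covariate maps): origin at the top-left corner, pixel
centres at half-cell offsets, x east / y north in metres. There is no CRS
handling or reprojection: inputs must already share a grid. Raster I/O uses
the plain-text ESRI ASCII grid format and vectors use GeoJSON, so every
artefact is diffable and portable without a binary GIS dependency.

Covariate layers (18): canopy closure (%), distances to forest, river,
road, settlement and industrial plantation (m), NDVI, percent forest within
250 m, mean and standard deviation of canopy closure and NDVI in 150 m and
500 m windows, population density (people/ha), and canopy height (m).

Two geometric choices matter and are deliberately documented because the
underlying GIS conventions are rarely stated:

* **Windows are circular on pixel centres** (radius in metres, focal pixel
  included), not square; edge windows use in-extent pixels only and `sd`
  is the population formula. A "250 m window" is read as radius 250 m.
* **Distances are exact pixel-centre Euclidean** (separable
  Felzenszwalb–Huttenlocher transform), not a chamfer approximation, so
  they can be tested against brute force to machine precision. Distances
  to rivers/roads are exact point-to-segment distances to the vector
  centrelines.

## The restoration scenario

`apply_riparian_buffer()` converts every non-water, non-settlement pixel
whose centre lies within `buffer_half_width` (default 60 m, read as 60 m
on *each* side of the centreline) of a river into forest. Restored pixels
receive canopy closure — and, by the same mechanism, NDVI — from the
current-forest donor distribution: the donor mean by default, or seeded
draws from the empirical donor values (`attribute_imputation = "sample"`).
The scenario stack recomputes distance-to-forest, percent-forest and all
canopy-closure/NDVI focal layers and copies everything else (the paper's
update list); canopy height is copied too, since a newly planted corridor
does not instantly attain forest canopy height.

Two provable properties anchor the engine: monotonicity (forest area never
decreases, distance-to-forest never increases, percent-forest never
decreases) and locality (pixels farther than buffer + 500 m — the largest
focal window — from every river are bit-unchanged). Locality holds as a
theorem *provided* the nearest baseline forest in the far field is closer
than the new corridor; in landscapes with large forest-free regions the
distance-to-forest layer can change far from the river because the
corridor genuinely becomes the nearest forest. The property test asserts
the premise before the bit-equality, and this caveat is the reason.

## Statistical cores and their numerical choices

All engines are implemented from first principles in the package (the
reference implementations in `MASS`/`lme4` serve only as independent test
oracles):

* **Wilks' Lambda** is det(W)/det(T) over the covariate subset; a singular
  total scatter raises a "degenerate covariates" error rather than
  returning silent infinities.
* **Greedy forward selection** adds, at each step, the candidate
  minimising Lambda, gated by the partial-F test
  `F = ((n-g-p)/(g-1)) (Lambda_p/Lambda_{p+1} - 1)` with entry threshold
  `p_enter = 0.05`. The threshold is not stated in the source material for
  this pipeline, so it is a documented, configurable default.
* **LDA** uses empirical class-frequency priors by default (uniform by
  flag); a near-singular pooled covariance is ridge-inflated by
  `1e-8 x trace` with a warning — scenario-edited stacks can contain
  collinear layers. Posterior ties at classification resolve to the first
  class in declared order.
* **Smooths** are natural cubic regression splines with basis dimension 4;
  their span contains all linear functions, so the GLM-vs-smooth F-test is
  a valid nested comparison.
* **Moran's I** defaults to inverse-distance weights, row-standardised
  (rook weights available for grid tests), with the normal-approximation
  variance. For an LDA fit the residual fed to Moran's I is the
  expected-class-score residual `r_i = s(obs_i) - sum_k s_k p_ik` with
  classes scored 1..K in declared order — a scalar, approximately
  mean-zero quantity under a calibrated model.
* **Proportional-odds regression** maximises the cumulative-logit
  likelihood by BFGS with analytic gradients on a parameterisation that
  keeps thresholds strictly increasing; with two categories it reproduces
  logistic regression to 1e-6. Coefficients larger than 15 in absolute
  value trigger a clean non-convergence (complete separation) error.
* **Random-intercept linear models** profile the variance ratio in closed
  form per group and optimise in one dimension. Estimation offers REML,
  but model comparisons use ML because REML likelihoods are not comparable
  across fixed-effect structures.
* **Richness classes** are quantile splits (median or tertiles) of the
  training counts with ties to the lower class; the cut-offs are frozen at
  fit time and reused for prediction, because the field's low/medium/high
  definitions live in unavailable supplementary material.

## The wellbeing index

Twenty indicators map onto five dimensions (basic material, health, social
relations, security, freedom of choice and action). Each indicator is
normalised to [0, 1] against its *declared theoretical* range — not the
sample range, which would make indices incomparable across surveys — and
reversed where lower is better (sickness). Each dimension score is the
mean of its indicators and the index the unweighted mean of the five
dimension scores, which is exactly the per-variable weighting
1/(5 n_dim). Consequently an indicator in a 6-indicator dimension moves
the index by exactly 1/30 per unit of its normalised value, an identity
the tests assert.

## What the synthetic generator emulates — and what it does not

The generator provides a stated world with the statistical structure the
analysis assumes, so every stage is testable without field data:

* a five-class landcover mosaic from a smoothed Gaussian random field
  thresholded at the requested class proportions (defaults: forest 0.35,
  grassland 0.20, cropland 0.40, water 0.02, settlement 0.03), rivers
  burned in as water along random-walk centrelines, six villages, one
  industrial plantation block;
* canopy closure per class from truncated normals matching the field plot
  statistics (forest 41.0 ± 16.4 with a 30% higher-closure "woodland"
  stratum at 43.5 ± 14.1, grassland 8.2 ± 13.9, cropland 10.7 ± 12.9) —
  woodland is treated as a canopy-closure stratum of forest because the
  landcover map has no sixth class;
* plot microclimate from the calibrated linear model (slope −0.117 °C per
  % closure from a 36.5 °C open-ground intercept, residual sd 3.76 °C —
  the value that reproduces the reported 22.5% deviance explained when
  closure spans 0–60%);
* species detections whose per-taxon richness is Poisson with
  log-intensity linear in a landscape covariate (mammals load positively
  on percent forest, birds negatively); conflict events sampled on
  cropland proportionally to a risk surface (defaults 308 presence / 97
  absence); and households whose ordinal perception score follows the
  proportional-odds model with coefficients +2.43 (wellbeing index) and
  −0.51 (woman), thresholds fixed at (−1, 0, 1, 2) — chosen once so all
  five categories are populated, not tuned.

The generator does **not** reproduce the real geography, elephant
movement behaviour, detectability, seasonality, or the unreleased survey
data. A green test therefore establishes that the *pipeline recovers the
structure it was told to assume* at realistic sample sizes — not that the
published habitat-level map values are reproduced, which would require the
field data.

## Known limitations

* LDA assumes shared within-class covariance; no quadratic discriminant
  or occupancy/detectability modelling.
* The conflict model ignores fencing/mitigation and rainfall or cropping
  seasonality, matching the source framework's stated assumptions.
* No CRS support; planar grids only.
* Per-plot change subsets reported for the real landscape depend on the
  field data and are not reproduction targets here.

## A minimal run

```{r}
library(restoscape)
cfg <- default_pipeline_config(seed = 1, n_rows = 100, n_cols = 100,
                               out_dir = "run1")
manifest <- run_pipeline(cfg)
```

The manifest lists every output (landcover and covariate grids, fitted
model diagnostics, baseline/scenario probability surfaces, the high-risk
change mask and legend, change tables, household survey and model
comparisons) with md5 checksums; identical configs give identical
checksums.
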