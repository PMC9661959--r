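# restoscape

Forest landscape restoration (FLR) promises ecological *and* social
benefits, but its planning tools rarely predict both. `restoscape`
implements a systems-approach framework for evaluating a concrete
intervention — riparian forest buffers of 60 m on either side of river
centrelines in a mixed forest–agricultural landscape — **before any tree
is planted**, by propagating the changed landscape configuration through
three statistical pathways and mapping where benefits and costs land:

1. **Microclimate & crops** — ground/leaf surface temperature, leaf
   fluorescence and crop yield as functions of canopy closure `c`:
   Gaussian GLM `y = β₀ + β₁c + ε` vs a regression-spline smooth `y =
   f(c) + ε`, the simpler model kept unless a nested F-test rejects it.
2. **Biodiversity** — richness classes and threatened-species presence
   modelled by linear discriminant analysis (LDA) on landscape covariates
   after a Pearson collinearity filter (|r| < 0.7) and greedy forward
   selection on Wilks' Λ = det(W)/det(T), gated by the partial-F test
   `F = ((n−g−p)/(g−1))(Λ_p/Λ_{p+1} − 1)`; residual spatial structure
   checked with Moran's I.
3. **Conflict & wellbeing** — crop-raiding presence/absence via the same
   selection + LDA pipeline, yielding a per-pixel risk surface; household
   wellbeing as a composite index over 20 indicators in 5 equally
   weighted dimensions; village random-intercept models for damage/gender
   effects and a proportional-odds model
   `logit P(Y ≤ k) = θ_k − β·x` for the ordinal (0–4)
   perception-of-nature score.

A seeded synthetic-landscape module generates landcover mosaics, covariate
fields, species pools, plot/point surveys, conflict events and household
surveys with the statistical structure the analysis assumes, so the whole
pipeline is testable end to end without field data. Rasters are plain-text
ESRI ASCII grids, vectors GeoJSON — no binary GIS dependency.

Who it is for: restoration ecologists and socio-ecological modellers who
want a reproducible, fully tested reference implementation of this
pipeline to adapt to their own landscapes.

## Worked example

```r
library(restoscape)

b  <- generate_landscape(grid_spec(100, 100), seed = 1)   # 3 km x 3 km
st <- build_stack(b)                                      # 18 covariate layers

## conflict events concentrate near forest on cropland
crop <- b$landcover$values == match("cropland", LANDCOVER_CLASSES)
risk_true <- raster_grid(b$landcover$spec,
                         plogis(1.5 - st$layers$dist_forest$values / 120))
ev  <- simulate_conflict_events(risk_true, seed = 2, cropland_mask = crop)
pts <- extract_stack(st, ev$x, ev$y)
p3  <- fit_pathway3(ev, pts[, c("dist_forest", "dist_river",
                                "dist_settlement", "pct_forest_250",
                                "ndvi", "pop_density", "canopy_height")])
p3$selection$selected
#> [1] "dist_forest"

## 60 m riparian buffers, rebuilt covariates, risk before vs after
lc2 <- apply_riparian_buffer(b$landcover, b$rivers, scenario_config(60))
st2 <- rebuild_scenario_stack(b, st, lc2, scenario_config(60))
rb  <- predict_risk(p3$model, st); rs <- predict_risk(p3$model, st2)
sprintf("mean crop-raiding risk on cropland: %.3f -> %.3f",
        mean(rb$values[crop]), mean(rs$values[crop]))
#> [1] "mean crop-raiding risk on cropland: 0.718 -> 0.791"
table(HIGH_RISK_CATEGORIES[high_risk_change_mask(rb, rs)$values[crop]])
#>    new_high stable_high  stable_low
#>         139        3424         490
```

The forward selection recovers `dist_forest` — the covariate that
generated the events — and the riparian corridors, which cross the
cropland, pull 139 cropland pixels above the p > 0.5 high-risk threshold:
the spatially explicit cost side of the restoration trade-off.

The social pathway, on a simulated 461-household survey in six villages:

```r
hh  <- simulate_households(461, seed = 3)
idx <- composite_index(normalize_indicators(hh))
pm  <- perception_model(hh$perception, idx$index, hh$respondent_gender,
                        hh$village, hh$crop_damage_wildlife,
                        hh$crop_damage_elephant)
pm$aic
#>             model      AIC
#>          baseline 1464.300
#>         wellbeing 1442.689
#>            gender 1451.322
#>  wellbeing_gender 1434.660
#>              full 1437.949
```

Wellbeing + gender beats the village-only baseline by ~30 AIC while
adding the damage flags (generated with zero effect) does not improve it
— the fitted wellbeing coefficient on this single survey is 3.09
(generator value 2.43, single-survey se ≈ 0.35).

A full end-to-end run (landscape → covariates → fits → scenario →
prediction → change report, ~54 output files with a checksummed manifest):

```r
run_pipeline(default_pipeline_config(seed = 1))
```

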