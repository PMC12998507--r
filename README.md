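# peatfire

Fires in northern peatlands smolder in the organic soil itself, releasing
carbon stocks accumulated over millennia, persisting through winter in
"zombie" mode, and responding exponentially to dry, warm summers.
Quantifying them requires a long chain of methods: burned-area mapping from
multispectral composites, fusion with satellite active-fire detections,
clustering of burned pixels into dated fire events, attribution of burned
area to peatland, machine-learned estimates of burn depth and carbon
combustion, spatially correlated uncertainty propagation, and causal
statistics linking climate to fire. `peatfire` implements that chain as a
tested R package, exercised end to end on synthetic landscapes with known
ground truth, for researchers who want each rule of such a pipeline
explicit, seeded, and verifiable.

## What is implemented

* **Composites** — NDVI / NBR / NBR2, observation-level quality filters
  (cloud saturation, water floor, Landsat-5 stripe artifacts),
  minimum-NBR yearly compositing, and the 28-feature classification stack
  (9 post + 9 pre + 9 difference features + date difference).
* **Classification** — random forest (200 trees, min leaf 10, ≤450 nodes,
  √p variables per split, 50% bag fraction), burn probability as tree vote
  share, omission / commission / Dice validation.
* **Refinement** — seed confirmation above the burned-class mean
  probability, boolean region growing within 2 km of seeds
  (`P_b ≥ 40%` ∨ two spectral-change clauses), removal of patches with
  fewer than 4 seeds, 3×3 morphological cleanup.
* **Active-fire fusion** — footprint rasterization, Queen's-case appending
  of non-water active-fire pixels, Voronoi burn-date reassignment, and
  relocation of late-season detections to the previous year (≤5 km and
  strictly closer than same-year fires).
* **Fire patches** — spatiotemporal flood fill (16-day cutoff, 150-m
  bridging), tile-window processing with duplicate merging, overwintering
  flags (start before July 1 within 1 km of a previous-year patch), size
  summaries with the 1000-ha large-fire threshold.
* **Peatland** — area-conserving downscaling of coarse peat areas by a
  fine plausibility index; per-pixel and per-patch peat-fire attribution.
* **Emissions** — chained XGBoost models for burn depth, belowground and
  aboveground carbon combustion, with recursive feature elimination,
  budgeted hyperparameter search, and strictly out-of-fold repeated
  cross-validation; per-pixel prediction and emission aggregation.
* **Uncertainty** — Matérn-3/2 Gaussian process
  (`k(d) = (1 + √3d/ℓ)e^{−√3d/ℓ}`, ℓ = 25 km, hard cutoff) with
  heteroscedastic pixel noise, posterior `K − K(K+D)⁻¹K`, and a Nyström
  low-rank path (`K̃ = K_nm K_mm⁻¹ K_mn`, Woodbury identity) that never
  materializes the full kernel.
* **Climate statistics** — summer z-score anomalies against a 66-year
  baseline, exponential fits `log(BA) = a + bz`, Mann-Kendall trends with
  Sen slope, and a piecewise SEM (mixed models with zone random
  intercepts, d-separation basis set, Fisher's C on 16 df).
* **Synthetic landscapes** — a seeded generator producing every input
  above with known truth: dated reflectance stacks, planted overwintering
  and late-season scars, active-fire records along progression fronts, a
  peat index with coarse area constraint, 894 calibrated field plots
  (depth–combustion r = 0.75, provenance 285:568:41), and a 23-year
  climate series with a causal-graph zone panel.

See `vignettes/peatfire-methods.Rmd` for the models, assumptions, and
numerical choices.

## Worked example

```r
library(peatfire)

cfg <- sim_config(rng_seed = 42)          # 128x128 grid, 3 years, 30-m pixels
sim <- simulate_scenes(cfg)
res <- run_fire_pipeline(sim)

acc <- res$accuracy[[2]]
sprintf("year 2: omission %.2f%%, commission %.2f%%, dice %.3f",
        acc$omission_error, acc$commission_error, acc$dice)
#> "year 2: omission 0.20%, commission 0.00%, dice 0.999"

100 * res$peat$peat_fraction              # share of burned area on peatland
#> 44.3  48.5  16.9

sum(res$overwintering[[2]]$overwintering) # planted zombie fire found in year 2
#> 1

100 * res$relocation_recovery             # late-season pixels moved back
#> 100
```

Omission and commission are measured against the generator's scar masks:
the classifier plus refinement recovers essentially every burned pixel
with no false detections on these separable scenes (real imagery is much
harder; the point is that every rule fires exactly as specified). The
peat fractions are per-year shares of burned area falling on the
downscaled peat mask, and the overwintering flag finds the one scar
planted before July 1 within 1 km of a previous-year fire.

The climate arm:

```r
cl <- simulate_climate_series(cfg)
an <- summer_anomalies(cl$monthly, cl$baseline_monthly)
f <- fit_exponential(cl$annual$peat_ba, an$z$wd)
sprintf("log(BA) = %.2f + %.2f z (R2 = %.2f)", f$a, f$b, f$r_squared)
#> "log(BA) = -0.05 + 0.74 z (R2 = 0.79)"

sem <- piecewise_sem(cl$zones)
sprintf("Fisher C = %.2f on df = %d (p = %.2f)",
        sem$fisher$C, sem$fisher$df, sem$fisher$p_value)
#> "Fisher C = 20.71 on df = 16 (p = 0.19)"
```

The exponential fit recovers the generator's climate–fire link (truth
b = 0.9 here, estimated within sampling error at n = 23), and the SEM's
d-separation test does not reject the ten-path causal graph the panel was
generated from.

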