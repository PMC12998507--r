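---
title: "Methods: burned-area mapping, peat-fire attribution, and fire carbon emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burned-area mapping, peat-fire attribution, and fire carbon emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatfire)
```

`peatfire` implements, end to end and on synthetic landscapes with known
ground truth, an analysis pipeline for high-latitude fires in
peat-dominated regions: mapping burned area (BA) from multi-date
reflectance stacks, refining it with rule-based region growing and
active-fire fusion, clustering burned pixels into dated fire events,
flagging fires of overwintering origin, attributing burned pixels to
peatland through area-conserving downscaling, estimating burn depth and
carbon combustion with gradient-boosted models, propagating model
uncertainty to annual emission totals with a Gaussian process, and relating
annual peat BA to summer climate through exponential fits and a piecewise
structural equation model (SEM).

This vignette explains each model, its assumptions, the parameters that
matter, and the numerical choices, in the package's own terms.

## The planar grid

All rasters are plain R matrices on a planar grid of square 30-m pixels.
Pixel centers sit at `(col - 0.5, row - 0.5) * pixel_size` meters, so every
metric rule (the 150-m clustering bridge, 1-km overwintering vicinity, 2-km
seed vicinity, 5-km relocation proximity, 25-km correlation length)
translates directly to Euclidean distances in meters. Nothing in the
method depends on projection machinery, so none is used: real deployments
would swap the matrix container for a geospatial raster without touching
the rules.

## Synthetic landscapes

`simulate_scenes()` generates, per year, `n_obs = 8` six-band surface
reflectance scenes (blue, green, red, NIR, short SWIR, long SWIR) on days
75–320 of the March–November observation window. Reflectance is
piecewise-constant archetypes — vegetated, burned, water, cloud — plus
Gaussian noise (sd 0.01). This is deliberate: the classification stage
needs separability and controlled confusion, not radiative-transfer
realism, and the archetypes are chosen so the fire signal behaves
correctly: burned pixels drop in NIR and rise in long SWIR (so their NBR
falls, which is what minimum-NBR compositing keys on), clouds exceed the
NIR/SWIRL saturation filters, and water sits below the 0.005 red/NIR
floor. What passing tests on these scenes demonstrate is that the *rules*
are implemented correctly — they say nothing about spectral confusion in
real imagery, where burned/unburned separability is far weaker.

Fire scars are ellipses with a per-pixel burn day growing from the center
outward over 14–24 days. Three kinds are planted:

* **main** scars igniting in July–September;
* one **overwintering** scar per year pair: ignition before July 1
  (days 155–175), placed 450–800 m edge-to-edge from a previous-year scar,
  so the overwintering rule (start before day 182 and within 1 km of a
  previous-season fire) has known positives, while main scars (ignition
  ≥ day 186) can never be false positives;
* one **late-season** scar per year: ignition on day 331, after the last
  observation of its true year, so it surfaces in the *next* year's
  composites. These are the planted relocation cases.

Active-fire records are sampled every 4 days along each scar's progression
front (up to 3 points per front day), with the true burn day. At desk
scale the records carry one-pixel (30 m) footprints so that the active-fire
evidence matches the mapping grid; painting full 375-m footprints on a
3.8-km grid would wrap every scar in a 6-pixel halo and swamp the
commission statistics that the synthetic run is meant to expose. The
footprint-rasterization logic itself is exercised at the real 375-m size
in the unit tests.

Scar placement is greedy: candidate positions (half proposed from
peat-dense ground) are scored by how close the cumulative peat share of
burned area comes to the configured target of 43.6%, the kind of
peat-dominated fire season the pipeline is designed to quantify.

## Composites and the 28-feature stack

Indices are the standard normalized differences: NDVI (NIR, red), NBR
(NIR, long SWIR), NBR2 (short SWIR, long SWIR). Observations are dropped
when long SWIR > 0.3 or NIR > 0.33 (cloud saturation), red or NIR < 0.005
(water), or — only for Landsat-5 scenes of 2001–2002 (`sensor_tag =
"L5_early"`) — NBR2 < −0.3 (diagonal stripe artifacts). Filters apply per
observation before compositing, so filtering and index computation
commute.

The yearly composite keeps, per pixel, the surviving observation with the
*minimum* NBR (the strongest fire signal); ties break toward the earliest
day by processing observations in ascending day order under a strict
improvement rule. The classification stack holds 9 post-year features
(6 bands + 3 indices of the selected observation), the same 9 for the
previous year, their 9 differences, and the date difference between
compositing dates (+365 days across the year boundary): 28 features. The
9 + 9 + 9 + 1 decomposition is the only one consistent with that count.

## Classification and refinement

The burn classifier is a random forest with 200 trees, minimum leaf
population 10, at most 450 terminal nodes per tree (`maxnodes` — the
closest available mapping of a per-tree node budget), `sqrt(p)` candidate
variables per split, and a 50% bag fraction. It is trained once on labeled
pixels of the first analysis year (every valid pixel inside small
rectangular polygons of each class) and reused across years, assuming the
fire signal is independent of the time dimension. Training rows and
feature columns are canonically ordered before fitting so that the fit is
invariant to sample-order permutations under a fixed seed.

Refinement proceeds in four steps:

1. **Seeds**: classified pixels whose burn probability strictly exceeds
   the mean probability of the burned training class.
2. **Region growing** to a fixed point: a pixel joins when it is
   8-connected to the current region, lies within 2 km of a seed, and
   satisfies `P_b ≥ 0.40`, or `NBR2post ≤ 0.06 & NBR2diff ≤ 0.005 &
   Reddiff ≥ 0.04 & NIRdiff ≤ −0.003`, or `NBR2post ≤ 0 & NBR2diff ≤ 0.01
   & Redpost ≤ 0.03`. Growth requires contiguity, not merely proximity —
   proximity alone would flood disconnected qualifying pixels — and the
   converged mask is visit-order independent and monotone in the seed set.
3. **Seed-count filter**: connected patches with fewer than 4 seeds are
   discarded.
4. **Morphology**: 3 × 3 dilation–erosion, then erosion–dilation (90-m
   kernel at 30-m pixels). The operator order follows the reference
   procedure's own parenthetical definitions, which swap the standard
   opening/closing terminology; the literal sequence fills single-pixel
   holes first and then removes isolated pixels.

## Active-fire fusion

Records are rasterized by painting the pixels whose centers fall inside
the footprint rectangle; overlaps keep the earliest day. Active-fire
pixels 8-connected to a burned patch are appended (iteratively, so chains
attach) unless the pixel's own annual water cover is ≥ 80%. Every burned
pixel is then re-dated with the day of its nearest active-fire record
(Voronoi assignment; ties toward the earlier day), keeping the composite
day as a low-confidence fallback when a year has no records. Finally a
pixel detected in year *t* is relocated to *t − 1* when a previous-year
active fire lies within 5 km (inclusive) and is strictly closer than any
active fire of year *t* — the correction for late-season fires that only
become visible the following year.

## Fire patches and overwintering

Patch clustering is a spatiotemporal flood fill: pixels belong to the same
patch iff linked by a chain of neighbor pairs with burn-day difference at
most 16 days (the optimum of the 12–24-day trial range). Neighborhood is
Queen's-case, extended to any pixel pair within 150 m center-to-center so
that narrow rivers do not split events. The implementation is union-find
over offset-matched pixel pairs and is tested for exact equivalence
against a brute-force transitive closure. Large rasters can be processed
in tiles with a 3 × 3 rolling window (`merge_tiles()`), with duplicates
merged by pixel overlap; for patches smaller than a tile span the result
is identical to whole-raster clustering.

A patch is flagged as overwintering when it starts before July 1 (day 182,
exclusive; 183 in leap years) and its pixel set lies within 1 km
(edge-to-edge, measured between nearest pixel centers) of a previous-year
patch. The linkage records the nearest origin patch and whether peatland
is present in the corridor between the two patches (an elliptical buffer
around the closest pixel pair).

## Peatland downscaling and attribution

The peatland input is a continuous plausibility index in [0, 1] at fine
resolution plus a peat *area* per coarse unit. Within each unit the
highest-index pixels are selected until their cumulative area matches the
coarse area (rounded to the nearest pixel count; ties broken by ascending
cell index, so the result is deterministic). Conservation is exact to
within half a pixel per unit, and the selection is monotone in the index.
Units may be regular blocks or arbitrary labeled regions. Burned pixels on
the downscaled mask are peat fires; per-patch peat fractions and the
annual peat-BA series follow by counting.

## Burn depth and carbon combustion

Three chained gradient-boosted (XGBoost) regressions: burn depth (cm) from
42 candidate predictors; belowground carbon combustion (g C m⁻²) with the
*predicted* depth as an extra feature; aboveground combustion from a
43-predictor set that adds biomass. Feature selection is recursive
feature elimination: gain-importance ranking on the full set, nested head
subsets scored by 10-fold cross-validated RMSE, smallest-subset
tie-breaking. Exact duplicate columns are pre-screened (first in column
order wins) so the duplicate-column tie-break is deterministic rather than
left to the booster's arbitrary split choice. Hyperparameters are tuned by
a seeded random search over eight dimensions (learning rate, tree depth,
minimum child weight, row and column subsampling, L1, L2, boosting
rounds) under a 200-draw budget at full scale; the budget and the CV-RMSE
objective are what matter, not the optimizer's identity, so a Bayesian
optimizer would be a drop-in replacement.

Evaluation uses k-fold out-of-fold prediction repeated `repeats` times
(100 at full scale; desk runs and tests use 5, which changes only the
averaging noise), with per-plot predictions averaged across repeats. The
discipline is strict: no plot is ever predicted by a model trained on it,
and the depth feature entering the belowground model during evaluation is
the averaged *out-of-fold* depth prediction. At pixel scale the depth
model's direct prediction is used instead, since no cross-validation
exists at prediction time. Residual statistics (mean and sd of prediction
minus observation on the held-out averages) drive the uncertainty
propagation; negative pixel predictions are floored at zero and counted.

The synthetic field plots are calibrated to the field-compilation
conditions the models face in practice: 894 plots with provenance
proportions 285:568:41 (Alaska:Canada:Siberia), a sparse linear
depth link with noise sized so the depth model's repeated-CV R² lands near
0.5, and a belowground residual sd derived analytically so the sample
depth–combustion correlation is 0.75 under the provenance mix.

## Gaussian-process uncertainty

Combustion residuals are treated as Gaussian with the evaluation-phase
mean and sd. Each burned pixel carries an emission sd `σ_CC · A` (g C);
spatial correlation follows the Matérn-3/2 kernel
`k(d) = (1 + √3 d/ℓ) exp(−√3 d/ℓ)` with ℓ = 25 km, hard-zeroed beyond
25 km. The annual-total variance is `wᵀ P w` with `w` the per-pixel
emission sds and `P = K − K (K + D)⁻¹ K` the noisy-observation posterior
with heteroscedastic noise `D = diag(w²)`; the mean residual is subtracted
from the total as a bias correction. For large pixel sets the kernel is
replaced by its Nyström approximation `K̃ = K_nm K_mm⁻¹ K_mn` from `m`
uniformly sampled inducing points (1000 per batch at full scale), and the
prior inverse is applied through the Woodbury identity, so only `m × m`
solves and `n × m` products occur.

Two numerical points. First, the hard cutoff technically breaks positive
semi-definiteness; `K_mm` is therefore inverted through an
eigenvalue-truncated pseudo-inverse (relative tolerance 1e−10) rather than
a raw solve, which amplifies catastrophically for dense inducing sets on a
non-PSD kernel. Second, the low-rank factorization cannot represent the
cutoff discontinuity itself, so batches should be tile-local — spans
within the cutoff — which is also how the full-scale procedure batches by
processing tile. On a desk-scale grid (3.8 km ≪ 25 km) pixels are nearly
perfectly correlated, so the relative sd of the annual total approaches
the relative residual sd of the combustion model rather than shrinking
with the pixel count; that is the expected behavior of correlated errors,
not an artifact.

## Climate–fire statistics

Summer (June–September) means are z-scored against a 66-year baseline
(one mean and sd per variable, computed once). The climate–fire link is
`log(BA) = a + b·z`, fitted by OLS on the log scale by default (a
log-link Gaussian GLM on the untransformed response is offered;
log-OLS is the default because the reported fits are on log-transformed
BA). Zero-BA years are offset by half the smallest positive annual value
— the procedure is silent on zeros, and this keeps them in the fit without
dominating it. Monotone trends use the Mann-Kendall test with
tie-corrected variance and continuity correction, plus the Sen slope.

The piecewise SEM fits each endogenous node by its own regression:
ordinary least squares for the two drought proxies (Drought Code, PDSI as
functions of water deficit and minimum temperature), and linear mixed
models with a random intercept per geographic zone (west / central / east)
for log total BA, log peat BA, and belowground combustion. Coefficients
are standardized by grand (not within-zone) sds. Marginal R² is the
fixed-effects variance share; conditional R² adds the random-intercept
variance (so conditional ≥ marginal always). The d-separation basis set is
built by the standard missing-pairs construction — every non-adjacent node
pair, excluding exogenous–exogenous pairs and the two declared correlated
errors (total BA ~~ peat BA, whose raw and partial correlations are both
reported, and DC ~~ PDSI, which share weather forcing) — each claim tested
by adding the independent variable to the dependent node's model,
conditioned on the union of both nodes' parents. With the default
ten-path graph this yields exactly 8 claims, hence Fisher's
`C = −2 Σ log p` on 16 degrees of freedom. Mixed models use REML;
singular random-effect fits are reported, not suppressed, and an
unidentifiable mixed model falls back to ordinary regression with a
warning.

## Problem sizes and determinism

The package's reference study conditions — used by the test suite and the
acceptance script — are a 128 × 128 grid (3.84 km at 30 m), 3 analysis
years plus an unburned pre-year, 8 observations per year with 15% cloud
cover, 5% water, 30% peatland, 894 field plots, a 23-year climate series
with a 1958–2023-style 66-year baseline, and a 3-zone × 23-year SEM panel.
Statistical recovery suites use 200 seeded worlds for the exponential-link
slope, 1000 for the null rejection rate, and 40 for SEM sign recovery.
Every stochastic step is seeded; a fixed seed yields byte-identical
rasters and tables.

## Known limitations

* Reflectance archetypes make classification far easier than real
  imagery; accuracy numbers on synthetic scenes characterize the rules,
  not expected real-world skill.
* The peatland index is an input everywhere: the upstream model that
  produces it is out of scope, so downscaling inherits whatever biases
  that index carries.
* The residual sd entering the GP is constant per combustion model (a
  per-pixel heteroscedastic hook exists but the procedure does not
  specify how σ varies by pixel).
* The overwintering peat-corridor check uses an elliptical buffer around
  the closest pixel pair, one reasonable reading of "peatlands within the
  buffer zone".
* The 2-km growing vicinity is measured to the nearest seed (not the seed
  originating the growth front), and the 1-km overwintering distance is
  edge-to-edge; both alternatives would be small, documented changes.
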