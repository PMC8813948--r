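---
title: "Methods: ensemble range forecasting with dispersal on synthetic worlds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble range forecasting with dispersal on synthetic worlds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`treerange` implements the computational chain behind continental-scale tree
range forecasts: occurrence cleaning and spatial thinning, bioclimatic
predictor derivation, change-factor climate downscaling over a regional
climate model (RCM) ensemble, an ensemble species distribution model (SDM),
a stochastic cellular-automaton dispersal simulation, and land-use masking.
Because the real inputs (continental forest inventories, RCM archives, soil
and land-use grids) are too large to ship or recompute, every stage is
exercised on a fully synthetic world with known ground truth. This vignette
explains the models, the tunable parameters, the numerical choices, and —
importantly — what the synthetic studies can and cannot demonstrate about
behaviour on real data.

## The synthetic world

`make_world()` generates a 10 km-cell study region (default studies use a
100 x 120 grid, i.e. 1000 x 1200 km) with:

* monthly temperature (deg C): a north–south gradient (15 deg C span by
  default), a seasonal cycle peaking in July whose amplitude grows eastward
  (continentality), smooth spatially correlated "relief" noise (sd 0.6
  deg C), and independent smooth weather noise per month (sd 0.8 deg C);
* monthly precipitation (mm/month): wetter in the west, winter-peaking
  seasonality growing eastward, multiplicative smooth monthly noise (25%),
  floored at zero;
* soil pH (3.5–8.5) and organic carbon (g/kg) as smooth random fields.

The per-month noise deserves a note: without it, the derived seasonal
aggregates (annual total, summer/winter means, seasonality) are exact linear
combinations of one another, and the collinearity screen removes predictors
a species' niche is defined on. Real climatologies have month-to-month
weather that breaks this degeneracy, so the generator includes it.

Species are defined by Gaussian niches: suitability
$s(x) = s_{max}\exp(-\sum_v (e_v(x)-\mu_v)^2 / 2\sigma_v^2)$ over named
predictors. The standard study species uses mean annual temperature and
total annual precipitation with breadth $\sigma_v$ equal to 0.10 of the
predictor's within-domain range — a restricted-range species occupying
roughly a third of the domain, which is the regime where a continental
SDM study is informative. Occurrences are sampled cell-wise with
probability proportional to suitability times a region-wise sampling
intensity (default 4:1 west/east), mimicking country-level inventory effort
differences; coordinates are jittered within the cell.

Pseudo-RCM ensembles (`make_future()`) coarsen the world by block means
(factor 4, ~40 km, emulating the ~12.5 km-to-10 km scale gap of real RCM
work at a testable ratio) and perturb it: additive warming fields (ensemble
mean +3 deg C, between-model sd 0.5, within-model spatial pattern sd 0.4)
and multiplicative precipitation factors (mean 0.9, sd 0.05). The
generator emulates inter-model spread and smooth anomaly structure; it does
not emulate real RCM physics, topography, or the real European geography.

## Occurrence preparation

Four rules, in order:

1. **Dedupe**: at most one record per species per 10 km cell; the first
   record in stable input order is kept (determinism aids testing, and any
   residual choice is immaterial once thinning randomizes per block).
2. **Native-range trim**: records outside the species' range mask are
   dropped; designated species (the naturalized-alien case) bypass the mask.
   Masks here derive from true suitability, standing in for expert
   chorological maps.
3. **Minimum records**: species with fewer than 30 records (inclusive
   boundary: 30 is kept) are excluded. The filter is applied to the
   trimmed, pre-thinning counts, so eligibility reflects the full cleaned
   record set.
4. **Thinning**: per species, exactly one uniformly random record survives
   in each occupied 40 x 40 km block. The block lattice is anchored at the
   grid origin — any fixed anchor satisfies the rule; the origin is
   reproducible.

## Predictors and collinearity

`derive_bioclim()` computes, northern-hemisphere convention: mean annual
temperature `Mat` (deg C); summer (JJA) temperature `Ts` (deg C); winter
(DJF) and summer (JJA) precipitation `Pw`, `Ps` (mm/month); annual total
`Ptot` (mm/yr); seasonality `Pse` (sd/mean of the 12 monthly values, the
mean floored at 1 mm so arid cells stay finite); and continentality `Ci`
(warmest-month minus coldest-month mean, deg C — the standard
envirem-style definition, chosen because the source toolchain's exact
formula is not printed anywhere authoritative). Soil pH and organic carbon
pass through, completing the nine-predictor set.

`vif_screen()` removes collinearity stepwise: the layer with the largest
variance inflation factor (1/(1-R²) against all others) is dropped until
all are below 10 (the conventional default of the screening tools in this
field; configurable). Ties — infinite VIFs from exactly collinear pairs —
drop the later-listed layer. The screen is invariant to affine rescaling.
Growing-degree-days and humidity-index analogues are represented in the
analysis scripts by planted linear combinations; the real quantities are
not computed because the pipeline never uses them (they are screened out by
construction, exactly like their real counterparts were).

## Change-factor downscaling

Per month, on the coarse model grid: additive temperature anomalies
$\Delta T = T_{fut} - T_{ctl}$ and multiplicative precipitation ratios
$R = P_{fut} / \max(P_{ctl}, 0.1\,\mathrm{mm})$ capped at 10. The floor and
cap guard the ratio where control precipitation is near zero; the published
workflow is silent here, and uncapped ratios blow up desert cells.
Anomalies are regridded to the fine grid by bilinear interpolation
(cell-centre registration; destination centres outside the source-centre
hull clamp to the nearest centre so the fine domain can equal the coarse
domain) and applied to the fine baseline. Bilinear regridding reproduces
affine fields exactly and, when the baseline is the block-expanded control,
interior coarse-block means of the result match the coarse future — the
two properties the tests pin down.

## The ensemble SDM

* **Pseudo-absences**: a surface range envelope (per-climatic-predictor
  presence quantiles at q = 0.025, "inside" meaning within bounds on all
  predictors) defines the species' climatic region; 10,000 cells (scaled to
  2,000 in the desk-scale studies) are sampled uniformly without
  replacement outside it. Soil predictors stay out of the envelope: it is a
  climatic prior.
* **Prevalence 0.5**: absences are down-weighted by
  $n_{pres}/n_{abs}$ so total presence and absence weight balance, for
  every family that accepts case weights.
* **Families**: logistic GLM with linear+quadratic terms; GAM (thin-plate
  smooths, k = 4); gradient boosting (150 trees, depth 3, learning rate
  0.1, case weights normalized to mean 1 because the booster's
  regularization is not weight-scale-free); an additive MARS written for
  this package (forward hinge-pair selection by weighted least squares over
  quantile knots, GCV backward pruning with penalty 3, weighted binomial
  refit on the selected basis); a MaxEnt-style member implemented as
  ridge-penalized weighted logistic regression on linear+quadratic features
  only — mirroring the no-product/threshold/hinge restriction and the
  weighted-background equivalence of maxent to penalized logistic
  regression; and a probability random forest (500 trees, case weights).
  A family that fails to fit is flagged unusable and the run continues.
* **Integer maps**: probabilities are stored as integers 0–1000
  (`round(1000 p)`), the published convention.
* **Evaluation**: 5-fold spatial block cross-validation on 120 km blocks
  (three times the thinning scale, guaranteeing separation beyond the
  thinning distance), blocks assigned round-robin in seeded random order;
  each fold is scored at its TSS-maximizing threshold and fold TSS values
  averaged. TSS = sensitivity + specificity − 1.
* **Consensus**: members with cross-validated TSS above 0.7 (strict) are
  averaged; per-cell dispersion is sd/mean across retained members. The
  binary map thresholds the consensus at the TSS-maximizing threshold on
  the calibration points, ties broken toward the smallest threshold, and
  that current-period threshold is reused unchanged for all future
  projections.
* **Importance**: per predictor, 10 permutation repeats; importance is
  1 − mean Pearson r between permuted and reference predictions.
* **MESS**: the four-case percentile similarity per predictor, minimum
  over predictors; negative cells are non-analog and dropped from
  projections. A zero-range reference predictor yields similarity 100 at
  the constant and 0 elsewhere.
* **Projection modes**: a *climatic ensemble* (project once onto the
  ensemble-mean climate) and an *SDM ensemble* (project per RCM, then
  per-cell mean and sd, keeping cells with at least 8 of 11 — here,
  proportionally, `min_valid` of `n_rcms` — valid members).

## What the recovery studies show — and a saturation ceiling

On the standard study species the six families cross-validate at TSS
≈ 0.70–0.80 (the analysis scripts and the acceptance script print the
exact table), matching the skill level reported for real continental tree
SDMs, and permutation importance reliably ranks predictors the generating
niche never used last.

The consensus *probability* map, however, correlates with the graded
Gaussian truth at Pearson r ≈ 0.7, and it is worth being precise about
why. Under this calibration design the pseudo-absences exist only outside
the presence envelope, so inside it the optimal classifier output is ~1
regardless of how suitable a cell truly is; thinning additionally flattens
the within-envelope presence-density gradient that could have graded the
surface. Computing the Bayes-optimal probability surface for the design
(possible here because the truth is known) gives r ≈ 0.54–0.74 depending
on niche breadth — the fitted ensemble sits at that ceiling, i.e. the
plateau is a property of presence/pseudo-absence calibration, not a fitting
failure. Binary products (which is what the published maps are) are
unaffected; graded within-range suitability from this design should be
interpreted cautiously, on synthetic and real data alike.

## Dispersal

Trait-based distances: maximum dispersal distance (MDD) comes from a
log-log linear form per dispersal syndrome (wind/animal/unassisted) in seed
mass, plant height and terminal velocity, shipped as an editable
coefficient table with documented placeholder values of the right order for
trees; a per-species expert override takes precedence. The kernel's mean
distance is $10^{(\log_{10} MDD - 0.795)/0.984}$ — read with the outer
parentheses around the whole exponent, the only reading for which the mean
is below the maximum and $MDD = 10^{0.795}\,m$ maps to exactly 1 m.

The cellular automaton takes one step per 30-year period (maturity 1 step:
a 30-year step covers maturation, so colonists emit propagules from the
next step; propagule production 1): occupied cells that lost suitability go
extinct; each unoccupied suitable sink is colonized with probability
$1-\prod_i(1-p(d_i))$ over all sources within MDD, where
$p(d) = e^{-d/\alpha}$ with a hard cutoff at MDD — the kernel value is
used directly as a colonization probability, the convention of
cell-based CA dispersal models, making MDD a true maximum. Updates are
synchronous with pre-step sources (order independence), and a source must
itself be suitable in the current period to emit (a dying stand does not
reproduce). Bernoulli draws are consumed in row-major sink order from the
seeded stream, so runs are bit-reproducible. Thirty replicates are
averaged; a cell counts as occupied when at least half the replicates reach
it, and both the frequency raster and the majority binary are written so
neither reading of "averaged" is lost.

Categories compare initial occupancy, final suitability and majority final
occupancy: stable presence, decolonized (suitability lost), colonized, and
suitable-but-not-occupied (the dispersal-limitation signal). In the
pipeline the MDD is floored at 1.5 cell widths so the kernel can reach the
neighbouring cell centre at all — on a 10 km grid most tree MDDs are
sub-cell, and grid CA models parameterize their kernels at cell-distance
classes for the same reason. Even so, colonization on a 10 km grid is
rare: the synthetic studies reproduce the qualitative result that natural
dispersal, not climate, bounds future occupied range.

## Land use and outputs

Eight tree cover-fraction classes are summed, aggregated to the analysis
grid by exact area-weighted averaging, and binarized with a strict
threshold: forest where the summed fraction exceeds 0.40 (exactly 40% is
not forest — "above" is read strictly). Binary and category maps are
masked to 0, probability maps to nodata. The intermediate-emissions
scenario pairs with the "middle of the road" socioeconomic pathway tag as
published; the high-emissions pairing is not stated in the source workflow,
so it defaults to the "ssp5" tag, configurable and echoed in the run
report.

`run_pipeline()` chains everything for every species and period and writes
the published-style layout (`ens_clim/`, `ens_sdms/`,
`single_models/{bin,prob,CV}/`, `datasets/`, plus `dispersal/`), a flat
key-value config echo for provenance, and CSV/JSON reports. Rasters are
written as ESRI ASCII grids — a plain-text, tool-portable raster format —
with geotransform, nodata sentinel and a CRS tag (sidecar/manifest); no
reprojection mathematics is in scope, the tag is carried through
unchanged. Integer products use nodata 255.

## Problem sizes and determinism

The standard studies use a 100 x 120 grid (12,000 cells), ~4,000 raw
records thinning to ~300–400 calibration presences, 2,000 pseudo-absences,
5-fold block cross-validation, 10 importance repeats, 3 species, 3
pseudo-RCMs and 10 dispersal replicates in the orchestrated demo (30 in
the single-species study) — sizes chosen so a full run completes in
minutes on one core while every rule of the method is still exercised.
All randomness flows through explicit seeds (one seeded stream per
operation; stage seeds derived from the master seed), and the test suite
asserts bit-identical reruns of the whole pipeline.

## Known limitations

* The world is statistically, not geographically, realistic: no coastlines,
  mountains, barriers or real RCM physics; dispersal has no landscape
  resistance.
* The MDD coefficient table is a placeholder of the right order, not the
  published mixed-model fit (which would require the original trait
  database); it is configuration, and studies exercising the trait path
  state so.
* Graded suitability inside the presence envelope is weakly identified by
  design (see the saturation note above).
* CRS handling is a tag, not a projection engine; all grids in one run
  share one coordinate system.
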