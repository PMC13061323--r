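---
title: "Monthly burned-area mapping: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monthly burned-area mapping: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firescar)
```

## The problem

Rapid, monthly mapping of burned area from optical satellite imagery faces
three linked obstacles: persistent cloud cover (acute in the humid tropics),
spectral confusion between burn scars and other dark, low-vegetation
surfaces (notably wet exposed soils on mechanically cleared peatland), and
the multi-month persistence of scars, which causes the same fire to be
re-detected in consecutive monthly maps and double-counted. `firescar`
implements a processing chain that addresses each in turn: median
compositing over calendar-month windows, a supervised classifier over
pre/post-fire spectral change features, active-fire hotspot corroboration,
and an explicit repeated-burn ledger.

The chain processes one *reference month* at a time, in three steps.

### Step 1 — compositing

Two cloud-free composites are built per reference month from a Sentinel-2-
like stack of ten 20-m-capable bands (B2–B8, B8A, B11, B12; the 60-m bands
are excluded, and 10-m bands are aggregated to 20 m by 2×2 block means over
valid children):

* **pre-fire**: all valid observations in the three calendar months before
  the reference month. The long window secures enough cloud-free looks and
  a stable picture of pre-fire vegetation.
* **post-fire**: all valid observations within the reference month itself,
  so detected change is pinned to that month.

Aggregation is the per-pixel, per-band **median** of valid observations
(even counts average the two central values), which suppresses residual
haze, shadows and sensor artefacts. Validity is an explicit mask
everywhere; nodata never enters computation as a sentinel value. A pixel
with no valid observation in a window is *unobservable* that month — it is
excluded from classification and from area denominators, and can only be
picked up in a later month if the scar persists.

The Normalized Burn Ratio, NBR = (NIR − SWIR)/(NIR + SWIR), is computed per
composite. We use the native-20-m pair B8A/B12: the formula's band pair is a
package choice (the standard one for Sentinel-2), and B8/B12 is available by
argument. Healthy vegetation sits near +0.5; fresh char and ash drop below
−0.2; the ratio recovers over months as vegetation regrows.

### Step 2 — classification

Each pixel valid in both composites is classified burned (0) or unburned
(1) by a random forest over **22 features**: the ten bands plus NBR of each
composite, in a fixed, recorded order. Hyperparameters follow common
platform defaults — 100 trees, ⌊√p⌋ candidate features per split, minimum
node size 1 — with a seed carried in the configuration so the whole chain
is reproducible. No class reweighting is applied. Training spectra are
extracted from the composite pair of the month each point was labelled in,
the only self-consistent choice when points are labelled against monthly
imagery. The test suite shows the chain's conclusions are not sensitive to
tree count or split rule within reasonable ranges (51–100 trees behave
identically on the synthetic scenes).

### Step 3 — post-classification, four filters in fixed order

1. **Minimum mapping unit.** Connected components smaller than 6.25 ha —
   156 pixels at 20 m, the official Indonesian minimum burn-scar size —
   are removed, including isolated pixels. Components are 8-connected by
   default (scars are diagonally contiguous in practice); 4-connectivity is
   a configuration switch, and both are tested against a brute-force
   flood-fill oracle.
2. **Morphological refinement + NBR floor.** Opening with the 3×3 square
   structuring element, then closing with the 3×3 "circular" element. At
   3×3 the only element distinguishable from the square is the plus/cross
   (centre + 4 edge neighbours), which is what we use for "circular".
   Afterwards, any burned pixel whose post-fire NBR is strictly greater
   than −0.1 is returned to unburned: a pixel that still looks vegetated
   has very likely not burned. The boundary is strict — NBR exactly −0.1
   stays burned.
3. **Hotspot masking.** Burned patches are corroborated against daily
   active-fire detections. A patch survives only if at least one hotspot,
   dated within a window anchored at the reference month, lies inside the
   scar or within 100 m of it. The test is Euclidean distance from the
   hotspot point to the nearest burned-pixel centre; the *scar* is
   buffered, not the point, so sensor positional uncertainty (≈375 m
   VIIRS-like, ≈1 km MODIS-like) does not widen the acceptance region.
   The window length is configurable (`hotspot_window_months`), default 4
   (the reference month plus the three preceding months); a 3-month
   reading is available because operational descriptions of this window
   are ambiguous between the two.
4. **Repeated-burn masking.** A pixel detected as burned that was already
   newly burned in any of the previous 3 months (`lookback`, crossing year
   boundaries) is flagged `burned_repeat` rather than counted again; the
   rest become `burned_new` and enter the history. Masking is pixel-level,
   as the rule is worded, not patch-level. The history is stored as two
   per-pixel grids — month of last first-detection and number of
   first-detections — which is sufficient state for the lookback rule and
   for all area accounting, and scales to long runs where a per-pixel list
   of months would not.

The filter order is (1) → (2) → (3) → (4); the small-patch filter is not
re-run after later filters. The original description of step 2 labels the
two operations "dilation steps" while describing an opening and a closing;
we implement the opening-then-closing actually described.

### Accounting

* **burned extent** counts each pixel once across a run;
  extent = area burned once + area burned multiple times.
* **cumulative burned area** counts each pixel once per first-detection,
  `Σₖ k · area(k times burned)` ≥ extent.
* The monthly cumulative series is non-decreasing by construction.
* `aggregate_fraction()` produces coarse burned-fraction grids (factor 50:
  20 m → 1 km) over *observed* pixels only — a fully clouded coarse cell is
  NA, not 0. `zonal_area()` overlays zone masks (forest, peat).

## Validation machinery

`accuracy_assessment()` implements the standard stratified area-weighted
good-practice estimators. With strata = map classes, weights
`W_i = N_i / N`, and `n_ij` sample counts of reference class `j` in map
class `i`, the error matrix in area proportions is
`p_ij = W_i n_ij / n_i·`. Overall accuracy is `Σ p_ii`; user's accuracy
`UA_i = p_ii / p_i·`; producer's accuracy `PA_j = p_jj / p_·j`. Variances
use the stratified forms — `V(UA_i) = UA_i(1−UA_i)/(n_i·−1)`,
`V(OA) = Σ W_i² V(UA_i)`, and the producer's-accuracy variance with the
estimated reference-class totals — and 95% intervals are normal
approximations clipped to [0, 100]. Commission error is identically
100 − UA and omission error 100 − PA. The suite verifies unbiasedness and
92–98% empirical CI coverage over 500 stratified resamples of a map with
known error structure; at perfect agreement the interval degenerates to
zero width, which we document rather than widen.

`rebalance_sample()` repairs a sample drawn for one product when validating
another: per cross-stratum (monthly class × annual class) it subsamples
down or tops up to explicit targets. Targets are explicit arguments rather
than derived, because published adjustment recipes generally do not
uniquely determine the final counts.

`temporal_confusion()` reports the detected-versus-true burn month matrix,
exact-month agreement, and the rate of mismatches beyond one month.
`patch_sizes()` + `size_distribution_tests()` compare burn-size
distributions (Kruskal–Wallis, Kolmogorov–Smirnov, Mann–Whitney) above size
thresholds of 25/100/1 000/5 000 ha, marking a threshold not-applicable
when either sample is empty above it.

## The synthetic scene generator

Real national-scale imagery cannot ship with a package, so every stage is
exercised against `simulate_stack()`, which generates scenes with the
statistical structure the chain assumes, plus exact ground truth:

* **Spectra.** Three states (vegetation, fresh char, wet soil) with fixed
  mean reflectance per band and i.i.d. Gaussian noise (sd 0.012). The
  binding contract is NBR behaviour: vegetation ≈ +0.5, fresh burn ≈ −0.33,
  wet soil ≈ −0.24 — burn-like in NBR but separable in the visible and
  red-edge bands, so hotspot masking and hard-negative training both have
  real work to do.
* **Events** are connected footprints grown by randomised dilation from a
  seed pixel (90% of the frontier accepted per round), giving compact
  scars with mildly irregular edges — the regime the morphology stage is
  designed for. Events are mutually disjoint; repeated detection arises
  from scar persistence, and multi-burn accounting (k ≥ 2) is exercised
  with scripted maps.
* **Regrowth.** Burn severity decays as `s(t) = 0.5^(t/h)` months after
  the burn (default half-life h = 4 months); band means are the
  severity-weighted mix of char and vegetation spectra, so the NBR
  trajectory has a closed form that tests evaluate independently.
* **Clouds** are i.i.d. per-pixel validity failures at a configurable
  probability (default 0.2).
* **Hotspots** are emitted by each event in its burn month at a density per
  burned km², jittered uniformly within the sensor resolution (default
  375 m), with a configurable per-event miss probability; confuser patches
  never emit hotspots, and placement keeps them more than one jitter
  radius away from any event so the constraint is enforceable.

What the generator does *not* emulate — topography, smoke and haze
gradients, spatially correlated cloud, within-class spectral texture,
mixed pixels at scar boundaries, real FIRMS false alarms — bounds what a
passing suite shows: the chain's logic and estimators are correct under
the stated observational model, not that the published national accuracy
figures transfer to other data.

## Numerical and degenerate-input choices

* Median of an even number of observations: mean of the two central order
  statistics.
* NBR at NIR + SWIR = 0 is invalid (NA), never NaN propagation.
* The NBR floor and the hotspot buffer use strict `>` and `≤` respectively,
  with boundary cases pinned by tests.
* Nodata is an explicit validity mask; files declare a nodata sentinel that
  must not collide with data.
* Rasters are exchanged as Esri ASCII grids (text, georeferenced,
  nodata-aware) with an optional `.prj` sidecar carrying the CRS label;
  integer grids round-trip bit-exactly, floats at full double precision.
* Area arithmetic is always pixel counts × `pixel_area_ha()`
  (`pixel_size²/10⁴`; 0.04 ha at 20 m), so 6.25 ha ⇒ ⌊156.25⌋ = 156 pixels.

## Problem sizes used in the checks

The shipped verification runs use a 512 × 512 pixel grid (≈10.5 km square)
over 12 months with a 5-day revisit, 30% cloud, ten burn events of
30–200 ha and three wet-soil confusers — large enough for the minimum
mapping unit, the hotspot geometry and the stratified sampling to operate
at realistic scales, while a full simulate–train–map–validate cycle
completes in about two minutes. Under these conditions the chain recovers
total burned extent within a few percent (the residual is boundary pixels
trimmed by morphology — the chain is deliberately conservative), assigns
90–100% of events to their true burn month, and passes zero confuser area
through the hotspot filter.

## Known limitations

* Single-CRS, in-memory grids: no reprojection, tiling or out-of-core
  processing.
* The classifier consumes only per-pixel spectra; no texture or temporal
  features beyond the two composites.
* Omission under persistent cloud is intrinsic: an unobservable month
  cannot be mapped, only recovered later if the scar persists — matching
  the behaviour of the operational chain the package models.
* The generator's clouds are spatially uncorrelated, which is optimistic
  for compositing; correlated cloud would raise the unobservable fraction
  at equal cloud probability.
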