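---
title: "Burn-scar mapping from multi-date imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burn-scar mapping from multi-date imagery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firescar)
```

## The mapping problem

After a wildfire, the burnt surface changes its spectral signature in a
characteristic way: near-infrared (NIR) reflectance collapses as green
canopy is consumed, while middle-infrared (MIR) reflectance rises over char
and exposed soil. Given two co-registered multispectral acquisitions — one
before and one after the fire season — the burnt footprint can be separated
from unburnt land by thresholding a small set of biophysical indices and
confirming that the pixel actually changed between the dates. `firescar`
implements that chain end to end: from a pair of band stacks to a catalog
of burn-scar polygons with areas and land-cover attribution, plus the
area-based accuracy protocol and fire-regime summaries computed from the
catalog.

The chain has three phases, run in a fixed order by `run_pipeline()`:

1. **Pre-processing** — relative radiometric normalisation
   (`normalize_radiometry()`), rule-based cloud/water/shadow masking
   (`build_masks()`), change-vector analysis
   (`change_vector_magnitude()` + `change_mask()`).
2. **Core processing** — index thresholding fused with the change mask
   (`classify_burnt()`), with `calibrate_thresholds()` as an automated
   surrogate for supervised threshold selection.
3. **Post-processing** — majority (median) filtering, minimum-mapping-unit
   enforcement, raster-to-vector conversion with donut holes, event
   aggregation and attribution.

## Spectral indices and the classification rule

Four indices are computed (`nbr()`, `ndvi()`, `ndvi_multi()`, `albedo()`):

\[
\mathrm{NBR} = \frac{R_{NIR} - R_{MIR}}{R_{NIR} + R_{MIR}}, \qquad
\mathrm{NDVI} = \frac{R_{NIR} - R_{RED}}{R_{NIR} + R_{RED}},
\]
\[
\mathrm{NDVI}_{MULTI} = \mathrm{NDVI}_{pre} - \mathrm{NDVI}_{post}, \qquad
\mathrm{ALBEDO} = \frac{R_{NIR} + R_{RED}}{2}.
\]

All inputs are treated as opaque linear radiometric values (radiance, TOA
reflectance or digital numbers): the normalised ratios are unit-free and
the albedo proxy scales linearly, so no unit conversion is needed or
attempted. Pixels with a zero denominator become nodata rather than ±1 —
fabricating an extreme index value on a sensor artifact would propagate
into the classification.

A pixel is called burnt when **every enabled criterion** holds:
post-fire NBR ≤ `nbr_post_max` (default 0.0), multi-date NDVI ≥
`dnvdi_min` (default 0.3), post-fire NDVI ≤ `ndvi_post_max` (default 0.3),
optionally post-fire albedo ≥ `albedo_post_min` (disabled by default), and
— when `require_change` is on — the change mask flags the pixel. The
conjunction is the conservative reading of fusing index thresholds with a
change/no-change map; each criterion can be disabled independently, and
thresholds are expected to be retuned per sensor and landscape (they are
plain config values under `classify.*`). Pixels where the index criteria
and the change mask disagree are flagged in a diagnostics raster attached
to the classification, so an analyst can review exactly the pixels a
visual-inspection step would have looked at.

`calibrate_thresholds()` replaces interactive threshold picking with an
exhaustive grid search maximising the F1 score of burnt-pixel detection
over labelled sites; ties break toward the configuration that maps the
fewest burnt pixels (the most conservative map consistent with the
labels).

## Pre-processing choices

**Normalisation.** The default `pif_linear` method selects pseudo-invariant
features (PIFs) — unmasked pixels in the lowest quartile of the raw
change-vector magnitude — and fits one affine model per band mapping the
post scene onto the pre scene's radiometric scale, iterating the PIF
selection once. The slope is the *reduced major-axis* slope
\(\hat g = s_{pre}/s_{post}\) rather than the ordinary regression slope:
PIF pixels carry comparable measurement noise on both dates, and an
ordinary regression of pre on noisy post attenuates the gain toward zero
(severely so when the stable surfaces are spectrally homogeneous, as
radiometric differences then are mostly noise). The reduced major-axis
slope is symmetric in the two dates and coincides with the least-squares
slope in the noise-free case, so an exactly affine distortion
(`post = 2·pre + 5`) is still inverted exactly (gain 0.5, offset −2.5).
When the PIFs are constant in **both** dates the slope is underdetermined
and a pure offset (gain 1) is fitted; a constant post band against a
varying pre band is an error, as no meaningful model exists. Histogram
matching and `none` are available alternatives.

**Masking.** Cloud, water and shadow are screened with threshold rules on
a reflectance-like scale: cloud = bright and spectrally flat (albedo ≥
0.35 and NDVI ≤ 0.10); water = negative-NDVI and dark in NIR (NDVI ≤ 0 and
NIR ≤ 0.10); shadow = all bands ≤ 0.04. These defaults separate the
synthetic signature table cleanly and are deliberately simple — no
thermal-band or physically based cloud test is attempted. All five
thresholds live under `masks.*` and should be adapted to the sensor.
Masks may overlap; exclusion is their union, and both dates' masks are
OR-ed so a contaminant in either acquisition suppresses the pixel.

**Change detection.** The change-vector magnitude is the Euclidean norm of
the per-band difference (default bands RED/NIR/MIR). The default
threshold rule is robust: \(t = \mathrm{median} + k \cdot 1.4826 \cdot
\mathrm{MAD}\) with \(k = 3\) over unmasked pixels, i.e. approximately a
3-sigma outlier rule under a Gaussian no-change population. The comparison
is strictly `>` so that a perfectly unchanged scene yields an empty change
mask even though its MAD is zero. A fixed threshold is available for
sensors with known noise floors.

## Post-processing choices

* **Majority filter** (`median_filter()`, default 3×3, one pass): for a
  boolean raster the median and the majority coincide. Edges use
  reflection padding. Note one geometric consequence of the definition:
  the four corner pixels of a square scar see only 4 of 9 burnt
  neighbours and are shaved off, while straight edges and interiors are
  preserved — the filter trades a slight corner erosion for the removal
  of salt-and-pepper noise, exactly as the standard filter does.
* **Minimum mapping unit** (`remove_small_scars()`, default 1 ha):
  components whose pixel area is *strictly below* the MMU are dropped; a
  component of exactly the MMU is kept, matching a catalog that records
  fires of the minimum size and larger.
* **Connectivity** defaults to 8: on a 30 m grid, fire fronts routinely
  cross pixel corners, so diagonal pixels belong to one scar. A component
  whose pixels touch *only* diagonally is emitted as a MultiPolygon
  (several simple exterior rings) rather than a self-touching ring — ring
  tracing takes the sharpest right turn at pinch corners, keeping every
  ring simple and every feature valid.
* **Polygonization** traces pixel edges exactly, so polygon areas equal
  pixel counts times the pixel area to machine precision, and unburnt
  enclaves become interior rings whose area is excluded ("donut"
  polygons).
* **Aggregation** (`aggregate_scars()`) is opt-in (`aggregate_gap_m = 0`):
  the operational step it replaces was a manual grouping of nearby
  fragments into one fire event, so the automated surrogate — transitive
  closure over boundary distance ≤ gap — is off unless a gap is chosen
  deliberately. Geometries are never dissolved; fragments share an
  `event_id` and an `event_area_ha`.

## Validation protocol

`overlay_areas()` splits the detected and reference polygon unions into
detected burnt area (DBA), false burnt area (FBA) and skipped burnt area
(SBA); `accuracy_metrics()` then reports

\[
\mathrm{efficiency} = \frac{DBA}{DBA+SBA}, \quad
\mathrm{commission} = \frac{FBA}{DBA+FBA}, \quad
\mathrm{omission} = \frac{SBA}{DBA+SBA},
\]

with producer's accuracy = 1 − omission (identical to the efficiency) and
user's accuracy = 1 − commission. The omission denominator is DBA + SBA —
the reference area — which is the only definition consistent with the
identity producer's = 1 − omission used in published validation tables
(a variant with DBA + FBA in the denominator circulates and appears to be
a typographical slip; it would make the omission of a perfect-commission
map depend on false alarms). Metrics with a zero denominator are reported
as `NA`, never as 0: a layer with no reference burnt area has no defined
omission. Interior rings are excluded from all areas, so correctly mapped
unburnt islands are not charged as omission; all geometry in a layer is
pooled (events are not validated one by one).

The overlay itself is computed by coordinate compression: the plane is cut
at every vertex coordinate of either layer and each cell is classified by
its centre. For rectilinear geometry — everything this pipeline produces
traces pixel edges, and the validation fixtures are rectangles — the
result is exact; non-rectilinear input falls back to subdividing each cell
8×8, which is documented as approximate.

## Fire-regime analytics

`fire_size_distribution()` bins event areas into the standard size classes
(<10, 10–100, 100–1,000, 1,000–5,000, >5,000 ha by default);
`largest_n_share()` reports the dominance of the largest events;
`altitudinal_distribution()` tabulates burnt hectares over DEM zones
(0–500, 500–1,000, 1,000–1,500, >1,500 m by default); and
`landcover_proneness()` runs the Pearson chi-square comparing burnt area
per land-cover class against expectation proportional to each class's
landscape share, scaled to the year's total burnt area:
\(E_c = A_c / \sum_c A_c \times \text{total burnt}\), statistic
\(X^2 = \sum_c (O_c - E_c)^2 / E_c\) on \(k - 1\) degrees of freedom with
an upper-tail p-value.

Three conventions apply throughout and are worth stating once:

* **All intervals are half-open and lower-inclusive** `[lo, hi)`: a
  1,000 ha fire is a "1,000–5,000 ha" fire, a DEM value of exactly 500 m
  belongs to the 500–1,000 m zone.
* **Expected frequencies are normalised over the analysed classes only**,
  so observed and expected totals match (the standard Pearson setup). The
  ≥1%-share restriction used in published analyses is a caller-side
  filter, exposed as `min_share` and off by default.
* **Zonal sums rasterize the polygons at the DEM/land-cover grid** by
  pixel-centre membership instead of clipping polygons against pixel
  boundaries. For pixel-edge-aligned scars this is exact; otherwise the
  error is bounded by one pixel per boundary crossing. The simplicity (and
  exact agreement with the raster the polygons came from) was judged worth
  more than area-weighted clipping.

## The synthetic-scene generator

`simulate_scene_pair()` builds fixtures with known truth: a healthy
vegetated background (RED/NIR/MIR = 0.05/0.45/0.18), burn scars with the
burnt signature (0.08/0.12/0.30) inside contiguous irregular blobs —
discs along a short random walk, morphologically closed, then trimmed or
frontier-grown to exactly the requested pixel count — plus optional water
bodies (0.04/0.02/0.01, both dates), clouds (0.40/0.42/0.38, placed
independently per date) and additive Gaussian band noise clipped at zero.
The signature means were chosen so that the default thresholds separate
the surfaces *by construction* on noise-free scenes: burnt pixels have
post NBR −0.43 (≤ 0), multi-date NDVI 0.6 (≥ 0.3) and post NDVI 0.2
(≤ 0.3), while healthy pixels fail all three. Every generator is a pure
function of its parameters and a mandatory seed.

What the generator does **not** emulate: sensor point-spread functions,
atmospheric and BRDF effects, burn-severity gradients (the burnt signature
is uniform), phenological change between dates, topographic illumination,
and mixed boundary pixels. Tests passing on these scenes therefore
demonstrate the correctness of the chain's logic and geometry — not that
the default thresholds are right for any particular sensor; on real
imagery the thresholds are the analyst's responsibility.

One propagation effect is worth understanding because it shows up in the
noisy-recovery tests. With band noise σ = 0.02, the burnt-pixel post-fire
NDVI is 0.20 with standard deviation
\(\sigma_{NDVI} = \frac{2\sigma\sqrt{R^2 + N^2}}{(N+R)^2} \approx 0.15\)
(N = 0.12, R = 0.08: the small denominator amplifies band noise), so
roughly a quarter of burnt pixels individually fail the `ndvi_post_max =
0.3` criterion; the 3×3 majority filter recovers most but not all of
them, and a few percent more are caught by the water rule (burnt NIR
0.12 ± 0.02 against the 0.10 water bound). Omission at this noise level is
therefore inherently in the 10–20 % range for the default thresholds,
while commission stays near zero. The test suite asserts exactly that:
commission ≤ 10 % and omission ≤ 20 % averaged over fixed seeds — rather
than a tighter bound the default configuration cannot honour.

`simulate_reference_pair()` constructs rectangle layers whose overlay
yields exactly a requested (DBA, FBA, SBA) triple, and
`simulate_terrain()` builds spatially coherent DEM and land-cover rasters
with exact zone/class pixel shares by ranking a smoothed Gaussian field.

## Numerical and I/O choices

* Rasters are matrices with a `geo_grid` (square pixels, metre units,
  upper-left origin); indices are computed in double precision. Only
  projected, metre-unit CRSs are accepted — every area computation (MMU,
  hectares, overlay) assumes metres — and the CRS check is a documented
  heuristic on the identifier (the common geographic ids are rejected; no
  reprojection is attempted).
* Raster I/O uses the plain-text ESRI ASCII grid (`.asc`, one file per
  band) with a `.prj` sidecar carrying the CRS id and a JSON sidecar for
  scene metadata; vector I/O uses GeoJSON (MultiPolygon features, all
  attribute columns preserved; an empty catalog writes a valid empty
  FeatureCollection). Both formats are readable by standard GIS software.
* Connected components are computed as graph components over the
  pixel-adjacency edge list; the test suite cross-checks them against an
  independent flood-fill implementation, and the majority filter against
  per-pixel brute-force enumeration, exhaustively on small random grids.
* Problem sizes in the test and acceptance runs were chosen at desk scale:
  end-to-end recovery on 150–200 pixel square grids (≈ 2–4 km side at
  30 m), which exercises every code path — multiple scars, holes,
  contaminants — while keeping a full suite run under a minute.

## Known limitations

* No reprojection, orthorectification or geo-referencing: inputs must be
  co-registered on an identical grid in the same projected CRS.
* The overlay is exact only for rectilinear geometry; arbitrary reference
  polygons from external GIS are handled by cell subdivision
  (approximate).
* Thresholds are global per scene pair; no spatial stratification by
  landscape unit.
* Event aggregation is purely geometric (boundary distance); it knows
  nothing about ignition dates or administrative boundaries, which enter
  only as pass-through attributes.
* The chi-square proneness test treats hectares as frequencies, as is
  conventional in this analysis; its p-value inherits that convention and
  is best read comparatively across years, not as a calibrated error rate.
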