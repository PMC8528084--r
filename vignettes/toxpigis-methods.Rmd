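---
title: "Methods: ToxPi scoring, glyph geometry and hotspot analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ToxPi scoring, glyph geometry and hotspot analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxpigis)
```

## Scope

`toxpigis` turns a table of per-record indicator values (typically one row
per county) into: ToxPi slice and overall scores; geolocated radar-glyph
wedge polygons; multi-scale GeoJSON feature layers; and Getis-Ord Gi\*
hotspot classifications. This vignette documents the statistical model,
the geometric conventions, the numerical edge rules, and the choices made
where more than one defensible design existed.

## Scoring model

A **model** is an ordered list of slices; each slice has a positive weight
$w_i$, a domain (colour family) and one or more weighted, directed
components. Scoring proceeds in three steps.

1. **Cohort-relative scaling.** Each component column is linearly min–max
   scaled to $[0,1]$ over the non-missing entries of the input matrix
   itself. `lower_is_worse` components (protective factors such as
   vaccination coverage) are inverted as $1-x$ after scaling, so a larger
   scaled value always means a larger contribution. Scores are therefore
   *relative to the analysed cohort*: adding or removing records changes
   everyone's scores, which is inherent to the ToxPi framework rather
   than a quirk of this implementation.
2. **Slice scores.** $s_i = \sum_c w_c x_c / \sum_c w_c$ over the slice's
   components — a weighted mean with equal weights by default. The
   framework itself does not prescribe a sub-slice aggregation rule; the
   weighted mean is the simplest choice that preserves the $[0,1]$ range
   and weight-rescaling invariance at both levels.
3. **Overall score.** $S = \sum_i w_i s_i / \sum_i w_i \in [0,1]$,
   invariant under uniform rescaling of the slice weights.

**Edge rules** (all exercised by tests): a constant column scales to 0 for
every record rather than NaN, so glyphs stay well defined; missing values
are imputed as 0 *after* scaling — the most conservative possible
contribution — and reported via a message; both rules are deliberate
biases toward under-, never over-stating vulnerability.

**Group aggregation.** Group (e.g. state) profiles take the per-slice
*median* across members, and the group overall is *recomputed* from those
median slice scores rather than taken as the median of member overalls.
The two differ in general; recomputation was chosen so the drawn group
glyph and its reported overall score are always mutually consistent. Group
locations default to the mean of member coordinates.

## Glyph geometry

Glyphs are drawn in a projected coordinate system in metres so that a
glyph of a given radius covers the same ground area anywhere on the map.

* **Projection.** The package implements the ellipsoidal Albers equal-area
  conic projection (GRS80 ellipsoid) with forward/inverse formulas,
  shipping EPSG:5070 (Conus Albers, the default) and EPSG:3310
  (California Albers), plus a constructor for arbitrary Albers
  parameterisations. Equal-area was preferred over conformal
  alternatives because the glyph's *area* is its visual signal. The
  implementation is validated against independent ellipsoidal oracles:
  round-trips below $10^{-6}$ degrees, distance along a standard parallel
  (where conic scale is exactly 1) against `geosphere::distGeo`, and the
  equal-area property against `geosphere::areaPolygon`.
* **Angles.** Slice $i$ spans $360° \cdot w_i/\sum w$, clockwise from
  north, first slice starting at bearing 0° — the familiar ToxPi GUI
  orientation. The last slice absorbs the floating-point remainder so
  widths sum to exactly 360°.
* **Wedges.** A wedge ring runs centre → arc (one vertex at most every
  `arc_step` degrees) → centre and is closed. At the default
  `arc_step = 5°` the polygonised area is within 0.13 % of the true
  sector area $(\theta/2)r^2$ (the regular-polygon factor
  $\sin\theta_s/\theta_s$), comfortably inside the 0.2 % target while
  keeping file sizes small.
* **Radius floor.** `min_radius_fraction` (default 0.01) keeps zero-score
  slices as thin but clickable polygons, so interactive popups remain
  reachable; set it to 0 for strictly proportional radii (a vanishing
  internal floor of $10^{-9}$ still guarantees valid rings).
* **Subsets.** When a subset of slices is drawn, angles are recomputed
  from the subset's weights so the subset again tiles the full disc.

## Feature layers and GeoJSON

The layer builder produces the multi-scale product: a local glyph layer
(n·slices wedge features with raw component values attached for popups), a
density-reduced copy (same attributes, radius scaled by `shrink`), a
group-median glyph layer at a larger default radius, quantile choropleths,
and optional maximum-radius rings. Every feature carries its record id (or
group label), so hotspot results and raw data can be joined downstream.

Zoom-dependent layer switching is a renderer concern: layers carry only
*advisory* `scale_hint` zoom ranges, serialized into a JSON sidecar next
to each GeoJSON file together with the role, legend and colours — GeoJSON
itself has no standard slot for styling.

Choropleths use quantile class breaks ($k = 5$ by default): with no
distributional assumptions it guarantees occupied classes, at the cost of
data-dependent break positions. Ties can collapse classes (with a
warning). Group choropleth outlines default to the convex hull of member
boundary vertices — exact for convex groups such as the generator's
vertical bands, approximate for concave real-world states; supply real
group outlines via a boundaries GeoJSON where that matters.

All output is RFC 7946 GeoJSON: WGS84 longitude–latitude, closed rings,
counter-clockwise exterior rings (wedges are *drawn* clockwise in
projected space and re-oriented on write), coordinates rounded to 6
decimal places (≈ 0.1 m, far below the arc-discretization error).

## Hotspot analysis

* **Weights.** Binary distance-band neighbourhoods with the band inclusive
  and self included, computed with haversine great-circle distance
  (mean Earth radius 6 371 008.8 m) on the *unprojected* coordinates —
  the neighbourhood structure is thus independent of the drawing CRS.
  Miles convert at exactly 1 609.344 m. The band is a required parameter
  (50 miles is a conventional county-scale choice); automatic band
  selection is out of scope.
* **Statistic.** The Gi\* z-score as defined above, evaluated per record.
  Degenerate denominators — constant values, or a band so wide every
  record neighbours every other — yield $z = 0$ with a warning rather
  than an error, since both arise naturally while exploring band sizes.
* **Significance and bins.** Two-sided normal p-values, optionally (and by
  default) Benjamini–Hochberg adjusted across records, then the seven-bin
  classification: $|bin| = 3/2/1$ at $p \le 0.01/0.05/0.10$, sign from
  $z$. Binning on p-values rather than fixed z cutoffs lets the FDR
  adjustment integrate cleanly; with FDR off it is numerically identical
  to the classic 1.645/1.960/2.576 thresholds. Whether published
  county-level dashboards applied such a correction is generally
  unstated, so both modes are provided; FDR-on is the default because
  hundreds of simultaneous local tests otherwise inflate the family-wise
  false-positive count.

## Synthetic data generator

`generate_lattice()` emulates county-like input: a regular
`n_cols × n_rows` point lattice (default 12×12, 30 km spacing — a typical
county-centroid separation — placed in the central United States), square
boundary cells, vertical-band "states" (contiguous column bands, earlier
bands one column larger when the division is uneven), and i.i.d.
Uniform(0, 1) baseline noise for every component of the bundled 4-domain /
14-slice vulnerability-style model. The bundled model's slice weights are
documented placeholders (all 1), since published vulnerability models ship
their weights as configuration rather than constants.

Planted clusters add an effect $\delta$ (default study condition
$\delta = 3$, radius 2 cells) to every `higher_is_worse` component of
records within a great-circle radius of the centre, *before scaling*, so
the effect propagates through the entire scoring chain. Uniform baseline
noise keeps min–max scaling well behaved.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: spatially correlated background noise,
heavy-tailed or skewed indicators, irregular county geometries and
centroid spacings, population-size heteroscedasticity, and missing-data
structure. The statistical guarantees (cluster recovery, null
calibration) are claims about the stated simulation conditions only.

## Verification strategy and problem sizes

The test suite checks every operation against independent oracles: a
separately coded brute-force double-loop Gi\* (agreement to $10^{-10}$
over randomized instances up to $n = 100$), a hand-coded haversine,
regular-polygon and shoelace area formulas, ray-casting point-in-polygon
for wedge disjointness, and `geosphere` ellipsoidal distance/area for the
projection. Statistical properties use fixed seed sets: planted-cluster
recovery on 12×12 lattices over 20 seeds (centre bin +3 required in ≥
18/20, corner bins ≤ 1 in magnitude) and null calibration over 50 seeds
(proportion of $|bin| \ge 2$ calls with FDR off consistent with the
nominal 5 % level by a binomial test at $\alpha = 0.01$). These sizes
give stable pass/fail behaviour while keeping the default suite around a
minute on one CPU.

## Known limitations

* Scores are cohort-relative; cross-cohort comparisons require re-scoring
  the pooled data.
* The CRS registry covers Albers parameterisations only; other projected
  systems would need new forward/inverse formulas.
* Gi\* inference uses the normal approximation, not conditional
  permutation; at very small $n$ or tiny neighbourhoods the approximation
  is rough (the binomial-calibration test bounds this under the study
  conditions).
* Overlapping glyphs in dense areas are mitigated only by the shrunken
  dense layer, not resolved by displacement.
* Group choropleth outlines are convex hulls unless real outlines are
  supplied.
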