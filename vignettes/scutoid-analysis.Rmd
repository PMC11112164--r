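---
title: "Detecting scutoids and quantifying 3D packing in spheroidal epithelia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting scutoids and quantifying 3D packing in spheroidal epithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scutoidr)
```

## The problem

A monolayered epithelium wrapped around a curved lumen cannot keep all of
its cells prism- or frustum-shaped. Cells can instead intercalate along
their own apicobasal axis — a neighbour exchange in space rather than in
time, the apico-basal T1 transition (AB-T1) — and the four cells involved
adopt the *scutoid* shape: their apical and basal neighbour sets differ.
Scutoid frequency is therefore a direct readout of how three-dimensional the
packing of a curved tissue really is, and how it responds to cell density,
compaction and proliferation.

`scutoidr` operationalises this readout for labelled 3D segmentation
volumes (one positive integer per cell, 0 background, anisotropic voxel
spacing in µm), the standard output of modern deep-learning segmentation of
confocal stacks of spheroidal embryos and cysts. Everything downstream of
segmentation is covered: layer extraction, scutoid calls, the per-cell
morphometric panel, tissue-scale curvature statistics, a matched 3D Voronoi
null model, and division-relative scutoid timing. A synthetic-epithelium
generator with exact ground truth makes every stage testable without any
imaging data.

## Detection model

**Layer extraction.** Arrays are ordered `(z, y, x)` with z index 1 the
slice closest to the objective. For every (x, y) column the *apical* label
is the first nonzero label met scanning z downward, the *basal* label the
first met scanning upward; the slice indices form apical and basal
heightfields. This directional-scan definition matches how objective-side
stacks of a spheroidal embryo are read: the scan enters through the outer
(apical) surface of the near cap and leaves through the inner (basal)
surface.

**Neighbour sets and scutoid calls.** On each 2D layer map every cell's
pixel set is dilated and the overlapped labels are its neighbours. The
default structuring element is the radius-1 disc under 8-connectivity (the
3×3 box): label maps are gap-free, so radius 1 finds every contact, and
corner-only contact deliberately counts as neighbourhood (the quartet
phantom inserts an explicit anti-diagonal wall so its separated pair is
never bridged by a corner). The relation is symmetrised by union and is
irreflexive. A cell is a **scutoid** iff its apical and basal neighbour sets
differ as sets. Cells with more than two distinct configurations along z
are out of scope; the call is binary apical-vs-basal.

**Selection band and borders.** Analysis is restricted to cells whose
centroid lies within `band_depth` (default 30 µm) of the apical heightfield
at the centroid's (x, y) — the well-imaged cells nearest the objective.
Distance is measured along z to the heightfield rather than in 3D to a
surface mesh; for the shallow caps this targets, the difference is
second-order. Cells whose apical or basal footprint touches the image
boundary carry truncated neighbour sets that would inflate the scutoid
count, so the default `border_policy = "exclude"` removes them from both
numerator and denominator; `"include-flagged"` keeps them with the flag
set. Both the dilation radius and the border policy are config-exposed
because reasonable segmentations can argue either way.

## Morphometric panel

* **Volume**: voxel count × `dz·dy·dx`. Conservation (Σ cells + background
  = grid volume) is exact by construction.
* **Convexity ratio**: cell volume over the volume of the convex hull of
  the 8 physical corners of every cell voxel. Corners — never voxel
  centres — guarantee the hull contains the voxel union, so the ratio is in
  (0, 1] and equals 1 exactly for axis-aligned cuboids. The hull is a
  quickhull over a pruned corner set (per corner column only the z-extremes
  can be hull vertices). Note that corner hulls are inflated by up to
  √3/2 voxel relative to the underlying smooth shape, so even a perfect
  digital ball scores below 1 (≈ 0.85 at radius 10 voxels, rising with
  radius); convexity values are comparable across cells at one resolution,
  not across resolutions.
* **Height**: Euclidean distance between the centroids of the cell's
  apical-surface and basal-surface pixels at their recorded depths.
* **Density**: counted cells over the sum of the basal areas they occupy.
  Basal area is the footprint pixel area corrected per pixel by the
  heightfield slope factor √(1 + (∂z/∂x)² + (∂z/∂y)²), because the inner
  surface of a curved cap is larger than its projection; flat tissues are
  unaffected.
* **Opening areas**: background connected components of the full 2D
  projection that lie inside the convex hull of the projected footprint
  (the exterior is not an opening), with a minimum-area threshold
  (`min_opening_area`, default 5 µm²) to suppress sliver components between
  the hull and the footprint. The threshold is a package default, chosen at
  roughly half a cell footprint pixel block; it is deliberately
  configuration, not biology.

## Tissue geometry

Apical and basal surface pixel clouds are fitted with general (rotated)
algebraic least-squares ellipsoids; imaged embryos are arbitrarily
oriented, so axis-aligned fits would be wrong. Before fitting, pixels of
the deepest slice of each surface are trimmed: at the rim of an imaged cap
the z-scan exits the segmented region through the lateral wall, producing a
flat artifact sheet that would otherwise dominate the basal fit.

At each selected cell centroid, projected radially onto each fitted
surface, the two principal curvatures (k_h ≥ k_w) follow from the shape
operator of the implicit quadric; they agree with the closed-form ellipsoid
curvatures to machine precision on exact fits. Radii R = 1/k are averaged
per surface and per axis class (h = greatest curvature, w = least), giving
the two apical/basal surface ratios SR_h = R_a_h/R_b_h and
SR_w = R_a_w/R_b_w. The **surface ratio anisotropy** is |SR_h − SR_w|: zero
for a tissue with isotropic curvature (concentric spheres), positive when
the apical-to-basal expansion differs between the two principal directions.
Averaging radii before taking the ratio is the default; the text
definitions admit the opposite order, so `sr_ratio_order =
"ratio_then_average"` is available for sensitivity checks. The absolute
value keeps the statistic non-negative.

The **tissue surface ratio** integrates each depth map as a triangulated
heightfield and divides apical by basal area (1 for a flat slab, R²-scaling
for concentric caps). **Embryo axes** come from an ellipsoid fitted to the
outer boundary of the hole-filled foreground: full lengths, aspect ratio
(longest/shortest) and major-axes ratio (longest/second-longest).

## The Voronoi null model

Each observed frame is compared against a steady-state geometric twin: the
binary mask of its labels is re-tiled by proximity to seeds placed at the
observed cell centroids, in physical distance with anisotropic spacing
honoured and ties resolved to the lowest label, so the construction is
fully deterministic. Observation and construction are then measured by the
*same* code path (layer extraction, band selection, scutoid detection), so
the excess of the observed scutoid proportion over the construction's is
attributable to geometry alone — the construction reproduces shape, density
and openings but no dynamics. The 30 µm band is recomputed on the
construction by default (`reuse_band = TRUE` reuses the observed
selection). Seeds falling in mask holes are kept, not projected. No Lloyd
relaxation is performed — a single proximity tiling is the model.

A construction analysed as an observed frame reuses its recorded seed set
(which, by construction, is the centroid set of its source frame), so the
comparison is idempotent: the rebuilt construction is bit-identical and the
excess is exactly zero. Note that re-deriving seeds from the construction's
own cell centroids would *not* reproduce it — discrete Voronoi tilings are
not fixed points of the centroid map — which is why the seed set travels
with the object.

## Scutoid timing relative to division

For tracked series with known interphase bounds (end of cytokinesis to
mitotic rounding), the first scutoidal frame of a cell within its
interphase is the onset, the end of that contiguous run the scutoid end.
Onsets normalise to `(onset − start)/interphase length`; durations count
inclusive frames. A run still scutoidal at the interphase end is
right-censored there and flagged, since the resolution of the transition
was not observed. A cell with two disjoint scutoidal runs in one interphase
is reported as an anomaly with both runs listed, never merged. Onsets
strictly before `onset_threshold` (default 0.15) of the interphase are
classed *after mitosis*, at or beyond it *independent* — the boundary value
itself is independent because the definition is "before", strict. The
developmental clock anchors relative time 0 and 1 at the first divisions of
two reference stages and splits each stage into a mitotic wave (ending when
≥50% of its cells have divided) and an interphase window.

Tracking uses persistent label ids (from the simulator or a supplied track
table); automated centroid matching of untracked series is left to the
caller, and interphase bounds are inputs, never inferred from images.

## The phantom generator

The generator emulates a blastula-like monolayer: an ellipsoidal shell mask
(voxel centres strictly between two concentric ellipsoids), seeds placed on
the mid-surface by a deterministic golden-angle spiral — quasi-uniform
density, like the embryo's epithelium — plus Gaussian jitter, and a Voronoi
tiling of the mask by those seeds. Jitter is applied *tangentially* and
re-projected onto the mid-surface: a monolayer keeps its cells in the
surface, and radial seed noise would manufacture apico-basal intercalations
everywhere, which is not the geometry being emulated. The
`view_halfangle` parameter keeps only the cap nearest the objective
(hemisphere by default in the study configurations), which is what an
objective-side stack actually captures — a full closed shell has no
reachable basal surface for the bottom-up scan. Openings are injected by
clearing all labels whose centroid direction falls within an angular cap.
Division series replace each dividing seed by two daughters offset ±half a
displacement along a random tangent and re-tile the same mask, recording
lineage and interphase bounds.

Default study conditions, stated here once and used by the validation
suite: spherical embryos with outer semi-axes 45 µm and inner 33 µm (12 µm
cell height, ~90 µm embryo — a typical early blastula), isotropic 1 µm
voxels so that a 192-cell hemisphere keeps ≥8 pixels per cell diameter
(matching confocal sampling relative to cell size), 1.5 µm tangential
jitter (mild positional disorder), synchronous waves 24 → 48 → 96 → 192
cells, and a *compressed* variant with outer semi-axes (49.5, 49.5, 27) µm
and inner (37.5, 37.5, 15) µm: axial compression to 0.6 with modest lateral
spread, preserving the 12 µm cell height while reducing the mid-surface
area by ~15%, the way confinement into a smaller space both flattens the
embryo and crowds its cells.

What the phantoms do *not* emulate: cortical tension, pressure balances or
any force-driven rearrangement (they are geometric, not biophysical),
protrusions, segmentation errors, intensity noise, or asynchronous
divisions. Passing tests on phantoms therefore validates the measurement
chain — that the pipeline measures packing correctly on known geometry —
not any biological claim about real embryos.

## Numerical choices and degenerate inputs

* Voxel membership everywhere is decided by the physical voxel-centre
  coordinate; one convention shared by masks, tilings and centroids.
* Voronoi ties go to the lowest label id (determinism without randomness).
* Quickhull uses a relative plane-distance tolerance of 1e-12 of the point
  spread; coplanar point sets are an error (convexity is undefined for
  cells spanning fewer than two slices).
* Ellipsoid fits centre and scale the data before the SVD, require ≥9
  points, and reject non-ellipsoidal quadrics; curvature at the fitted
  centre is undefined and an error.
* The transition depth of a quartet is the normalized z of the deepest
  slice still in the apical pairing; quartets without a unique pairing flip
  are an error, not a guess.
* Empty volumes, zero counted cells, zero basal area and missing stages
  all raise errors rather than returning NaN; `run_frame()` isolates
  per-stage failures into an error ledger so one bad frame cannot kill a
  series.
* Seeds are 32-bit; all generators are bit-reproducible given `rng_seed`.

## Problem sizes in the validation suite

The test and acceptance runs use hemispheres of 24–500 cells on grids up to
128³, twenty 32³ exhaustive Voronoi cross-checks, and ten replicate
spherical-vs-compressed series of four frames each; these sizes keep every
geometric feature resolvable (≥8 px per cell diameter, ≥8 slices per cell
height) while each full series stays in the seconds range.

## Known limitations

* Scutoid calls at the rim of the imaged cap are noisier than at the pole:
  rim cells are seen tangentially, exactly as in real objective-side
  stacks. The border policy and band selection mitigate but do not remove
  this.
* Convexity depends on resolution through the corner-hull inflation
  (above); compare within, not across, voxel sizes.
* The per-column band distance coincides with depth below the nearest
  embryo surface only for shallow caps.
* The Voronoi null inherits the observed segmentation's mask; segmentation
  errors propagate to both sides of the comparison (by design).
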