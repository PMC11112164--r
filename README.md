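# scutoidr

Scutoid detection and 3D packing morphometrics for curved monolayered
epithelia.

## What this solves

In a curved monolayer, cells need not keep the same neighbours on their
apical (outer) and basal (inner) surfaces: an intercalation along the
apicobasal axis — an apico-basal T1 transition (AB-T1) — turns the four
cells involved into **scutoids**, cells whose apical and basal neighbour
sets differ. The frequency of scutoids, together with cell density,
convexity, height, curvature anisotropy and epithelial openings, quantifies
how a proliferating spheroidal epithelium (an early embryo blastula, a
cyst) reorganises its 3D packing as it seals and compacts.

`scutoidr` takes labelled 3D segmentation volumes (integer label per cell,
0 background, multi-page TIFF with anisotropic µm spacing) and computes:

* **Scutoid calls** — apical/basal layer maps by directional z-scans; per
  surface, neighbour sets by label dilation (radius-1 disc,
  8-connectivity); a cell is a scutoid iff the two sets differ. Selection
  restricted to cells within a band (default 30 µm) of the surface nearest
  the objective; border cells excluded by default.
* **Morphometrics** — volume, convexity ratio (cell volume / volume of the
  convex hull over voxel corners), cell height, slope-corrected cell
  density (cells/µm²), opening areas.
* **Tissue geometry** — rotated least-squares ellipsoid fits of both
  surfaces; principal curvatures (k_h, k_w) at each selected centroid;
  surface ratio anisotropy `sra = |R_a_h/R_b_h − R_a_w/R_b_w|` (0 for
  isotropic curvature); tissue surface ratio (apical area / basal area);
  embryo axis lengths and shape ratios.
* **Voronoi null model** — the frame's mask re-tiled by proximity to its
  own cell centroids (deterministic, lowest-label ties) and measured by the
  identical pipeline, so `excess = observed − null` isolates what geometry
  alone cannot explain.
* **Division-relative timing** — scutoid onset/end within tracked
  interphases, normalized onsets and durations, after-mitosis
  classification (onset before 15% of interphase, strict), developmental
  clock with mitotic-wave windows.
* **Phantoms** — a synthetic spheroidal-epithelium generator (Voronoi cells
  of golden-spiral seeds on an ellipsoidal shell, division waves, openings,
  prism lattices and four-cell scutoid motifs) providing exact ground truth
  for every stage.

## Worked example

Generate a 150-cell hemispherical epithelium phantom (outer radius 45 µm,
cell height 12 µm, 1 µm voxels) and run the full per-frame analysis:

```r
library(scutoidr)

spec <- phantom_spec(outer_semiaxes = c(45, 45, 45),
                     inner_semiaxes = c(33, 33, 33),
                     n_cells = 150, spacing = c(1, 1, 1), jitter = 1.5,
                     rng_seed = 5, view_halfangle = pi / 2)
ep <- make_voronoi_epithelium(spec)
ep$volume
#> <label_volume> 96 x 96 x 96 (z,y,x), spacing 1 x 1 x 1 um
#>   150 cells

fr <- run_frame(ep$volume, run_config())
round(t(fr$summary[, -(1:2)]), 4)
#> n_cells            150.0000
#> n_selected         150.0000
#> n_counted          150.0000
#> scutoid_proportion   0.3667
#> density              0.0154
#> mean_volume        771.3867
#> mean_convexity       0.7230
#> mean_height         10.6944
#> sra                  0.0000
#> surface_ratio        1.1589
#> opening_area_sum     0.0000
#> voronoi_proportion   0.3600
#> excess               0.0067
```

Reading the numbers: 36.7% of the 150 counted cells are scutoids; density
is 0.0154 cells/µm² of basal surface; mean cell volume 771 µm³ and height
10.7 µm match the constructed shell (12 µm thick, ~770 µm³ per cell);
`sra ≈ 0` because concentric spheres have isotropic curvature;
`surface_ratio > 1` because the apical surface of a curved shell is larger
than its basal surface; no openings — the phantom is sealed. The matched
Voronoi construction scores 36.0%, so the excess attributable to anything
beyond static geometry is +0.7% here — as expected for a frame that *is* a
static Voronoi geometry:

```r
fr$null
#> <null_comparison> observed 0.3667 (n=150) vs Voronoi 0.3600 (n=150); excess +0.0067
```

Time-resolved analysis of a simulated division series, including scutoid
onset classification, runs through `run_series()`:

```r
base <- phantom_spec(c(45, 45, 45), c(33, 33, 33), n_cells = 24,
                     spacing = c(1, 1, 1), jitter = 1.5, rng_seed = 5,
                     view_halfangle = pi / 2)
ts <- timelapse_spec(base, n_frames = 4,
                     division_frames = list(`2` = "all", `3` = "all", `4` = "all"))
ser <- run_series(ts, run_config())
```

A thin command-line wrapper with subcommands `phantom`, `analyze-frame`,
`analyze-series`, `voronoi-null` and `dynamics` is installed at
`inst/cli/scutoidr`.

See the vignette (`vignettes/scutoid-analysis.Rmd`) for the detection
model, parameter meanings and defaults, the phantom design, and known
limitations.

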