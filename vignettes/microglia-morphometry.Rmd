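---
title: "Quantifying microglial morphology and tissue coverage with gliamorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial morphology and tissue coverage with gliamorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliamorph)
```

## The measurement problem

Microglia survey the brain parenchyma with a dense, hierarchically branched
arbor: roughly 7–9 primary processes leave the soma, branch into medium
processes, and end in very fine terminal processes a few micrometres long.
Ageing and amyloid pathology remodel this arbor — fewer bifurcations, fewer
and longer branches, unchanged territory — and the remodelling is best
captured not by any single number but by a panel of per-cell morphometrics
plus field-level coverage statistics. gliamorph implements that panel end to
end: per-cell measures on traced backbones, automated tracing from z-stacks,
field-level grid and Sholl analyses, per-cell marker-intensity
classification, and the group statistics used to compare conditions.

Because the microscopy underlying such studies is rarely deposited, the
package also ships a synthetic-data module that generates ground-truth cells
and fields and renders them into realistic noisy z-stacks. Every analysis
stage is validated against that ground truth; the synthetic conditions are
designed to reproduce the *qualitative* phenotypes (directions and rough
magnitudes of group differences), not any particular study's absolute
numbers.

## Per-cell morphometrics

A traced cell (`cell_trace`) is a rooted tree of 3-D points in micrometres
with SWC semantics. From it we compute:

* **Total branch length** \(L\): the sum of Euclidean edge lengths over the
  whole tree, in µm. No filter is applied to \(L\).
* **Branches**: maximal paths between consecutive topological nodes (soma,
  bifurcation, tip). Branches of length ≤ 0.5 µm are excluded from branch
  *counts* and from branch-length *histograms*, but still contribute to
  \(L\) — the minimum-length filter removes tracing debris without
  discarding signal.
* **Bifurcations**: non-soma nodes with \(k \ge 2\) children count as
  \(k - 1\) bifurcations. The soma is excluded because primary processes
  emanate from it rather than arising by splitting; a multifurcation is
  treated as the limit of closely spaced binary splits.
* **Tree area** \(A\): the area of the polygon through the outermost points
  of the arbor projected on the xy-plane — the convex hull of the projected
  nodes, in µm². Concave "territory" outlines are deliberately out of
  scope: the hull is the unique polygon through the outer points.
* **Depth** \(Z\): `max(z) − min(z)` over the nodes, µm.
* **Volume** \(V = A \cdot Z\) and **coverage volume**
  \(\mathrm{CV} = L / V \times 1000\): micrometres of process per
  \((10\,µm)^3\) cube of tissue. The ×1000 factor converts per-µm³ density
  to the \((10\,µm)^3 = 1000\,µm^3\) reference cube.
* **Thickness normalization**: cells imaged through different slice
  thicknesses are made comparable by scaling the extensive quantities
  (bifurcation count, branch count, \(L\)) by `20 / depth`. Area and CV are
  left untouched — CV is already volume-normalized. The scaling is linear in
  thickness, the simplest defensible rule.

`morphometrics()` returns one tidy row per cell, so groups assemble with
`dplyr::bind_rows()` and flow directly into `group_table()` and the test
layer.

## The synthetic generator

`generate_cell_trace()` grows a discrete random tree. Each segment (mean
length `segment_length_mean`, normal with floor 0.6 µm, discretised into
~1 µm polyline steps with angular jitter `tortuosity`) ends in one of three
events: **bifurcate** (probability `bifurcation_prob`, entering the next
branch order), **extend** (probability `extend_prob`, same order), or
**terminate**. Both probabilities may be per-order vectors, which is how
phenotypes that keep their primary scaffold but lose higher-order branching
are expressed. Independently, each segment endpoint can spawn a terminal
fine process of 1–4 µm with probability `fine_process_rate`. Orders are
capped at `max_order` (3: primary, medium, fine — the hierarchy seen in
cortical microglia).

Three structural constraints make the synthetic cells behave like cells in
sectioned, tiled tissue rather than free random walks:

* **Slab reflection** (`slab_z`, default 16 µm): growth reflects off the
  faces of a tissue-slab of fixed thickness, as real arbors are contained
  in (and truncated by) the section. This pins cell depth to the slab scale
  for every phenotype, which matters because depth enters CV.
* **Stratified elevations**: the primary processes jointly sample
  elevations spread across the slab instead of drawing them independently,
  so no cell degenerates into a planar pancake with near-zero depth (such
  outliers dominate CV variance otherwise, and are not seen in tissue).
* **Territorial taper** (`reach_radius` 22 µm, `reach_taper` 6 µm):
  continuation probabilities decay exponentially beyond `reach_radius`
  in-plane distance from the soma, emulating the bounded, contact-inhibited
  territories microglia maintain. This stabilises hull areas across
  phenotypes — the empirical observation the aged phenotype must reproduce
  is a *large* drop in branch length with only a *slight* drop in area.

Condition presets (young; aged; three plaque layers from amoeboid L1 to
mildly de-ramified L3) encode the phenotypes: the aged preset keeps 5–7
persistent primaries (`extend_prob` 0.95 at order 1) but nearly eliminates
higher-order branching and fine processes, yielding roughly half the branch
length at ~85 % of the territory. Where the literature gives no quantitative
per-order distributions, defaults were chosen once to land total branch
lengths (young ≈ 400 µm, aged ≈ 190 µm), hull areas (≈ 1200–1700 µm²) and
depths (≈ 14–16 µm) at magnitudes plausible for cortical microglia imaged
through a ~16 µm slab, and are not tuned thereafter.

`generate_field()` places somata by dart-throwing with a minimum spacing
(default 20 µm) and one independent RNG stream per cell derived from the
master seed and cell index — adding a cell never perturbs existing cells. A
plaque field assigns phenotype by concentric distance rings (layer radii
40 / 70 / 140 µm) and plants CD39-like channel-2 intensities: high for
layers 1–2, an even normal/low mixture for layer 3, the reference
distribution \(N(100, 15)\) elsewhere. The default density (12 cells per
(100 µm)²) was calibrated once so young fields are near-contiguously
covered (grid means of order 10 µm per square, vacant area of a few
percent); with territory-sized cells of ~400 µm arbor this density is
higher than stereological counts in tissue — the product of density and
per-cell length, which is what field statistics see, is what was matched.

`render_stack()` rasterizes every edge as a capsule with per-node radii,
blurs with a separable Gaussian PSF approximation (default σ = 0.3 µm) and
adds Gaussian noise (default SD = 5 % of the tube intensity) or Poisson
noise. Channel 2 scales each cell's tube intensity by its planted MFI. The
unblurred voxel→cell map is returned as ground truth. Voxel convention
throughout the package: voxel \(i\) (1-based) has its centre at
\((i - 0.5)\,d\); anisotropic voxels (default 0.25 × 0.25 × 0.5 µm; the
axial step matches typical confocal z-intervals) are respected in every
length computation.

## Automated tracing

`trace_from_stack()` binarizes at a user threshold and turns each
26-connected component into a rooted tree, rooted at the maximal
distance-transform voxel (the soma is the thickest structure) or at a
user-supplied soma seed.

Two engines are provided. The **skeleton** engine follows the classical
recipe — topology-preserving sequential 3-D thinning to a one-voxel curve
skeleton, a 26-connectivity graph with physical edge lengths, loops broken
by a minimum spanning tree (removing the longest edge of every cycle).
Curve thinning, however, has a known failure on flat-capped tubes: with
only endpoint preservation, a branch end can erode into a two-strand
hairpin and the junction disappears — the recovered tree then has the wrong
tip count. We therefore default to the **geodesic** engine: Dijkstra over
all foreground voxels with edge weights penalized by the chamfer distance
transform (so optimal paths hug tube centrelines), followed by iterative
farthest-point extraction — the farthest uncovered voxel seeds a path
backtracked until it enters the *tube zone* (a ball of radius equal to the
local distance-transform value) of an existing tree node, and each accepted
path voxel covers a ball of radius `cover_k · dt + cover_min`
(`cover_k = 1.6`, `cover_min` = 2 voxel widths). Terminal paths shorter than
`min_branch` (1 µm) are covered but not added. Because a rooted tree's
bifurcation count equals its number of tips minus the root's out-degree,
recovering tips robustly is exactly what exact topology recovery requires.

Both engines share post-processing: nodes inside the soma ball
(`soma_collapse` × the root's distance-transform radius) merge into the
root so primaries emanate from it; terminal spurs shorter than 2 voxels
(thinning/digitisation artifacts) are pruned before the 0.5 µm analysis
filter ever sees them; and interior chain nodes are relaxed by two rounds
of 1/4–1/2–1/4 averaging, which removes most of the voxel-staircase length
overestimate (raw digital paths overestimate smooth curve length by up to
~8 %).

`roundtrip_params()` documents the geometry under which tracing is
validated *exactly*: no fine processes, low tortuosity, tube radii at or
above the axial voxel size (a tube thinner than the z-step can pinch off
between planes), first bifurcations outside the soma-collapse ball, and
rejection-resampling until all tree-distant branches stay ≥ 2.5 µm apart.
Outside this regime — crossing branches, sub-voxel fine processes — tracing
errors are expected and quantified, not hidden: fine processes shorter than
the coverage margin (~2 µm) can be absorbed into their parent tube, and
crossing branches can swap connectivity.

## Field-level spatial coverage

The field pipeline mirrors standard practice: `max_projection()` (per-pixel
maximum over z), `threshold_binarize()` (Otsu on a 256-level histogram by
default — a reproducible stand-in for manual background elimination — with
a fixed-value override; the applied threshold is always attached to the
result), and `skeletonize_mask()` (Zhang–Suen two-pass thinning; symmetric
ribbons collapse to their midline, with end caps retracting by up to half
the ribbon width).

**Skeleton length** uses the exact step rule: each unordered pair of
8-connected skeleton pixels contributes one step — `pixel_size` for axial,
√2 · `pixel_size` for diagonal — and isolated pixels contribute one
`pixel_size`. Region-restricted lengths give boundary-crossing steps half
to each side, so lengths over any partition sum *exactly* to the total;
`grid_analysis()` exploits this to guarantee per-square conservation. The
grid is 32 × 32 squares of 25 µm² (5 µm side) anchored at the image centre;
squares with < 1 µm of process are *vacant*; the per-square distribution is
returned as a 1 µm-binned histogram.

`sholl_profile()` counts process–circle intersections at radii 40–140 µm in
5 µm steps (the ring between a plaque's edge and the average distance to
its neighbour). On a discrete skeleton an intersection is one 8-connected
pixel component inside a thin annulus; the annulus half-width is 0.75
pixels — the smallest band a digital curve cannot step across, since a
diagonal step changes radial distance by at most √2/2 pixels (a half-pixel
annulus demonstrably misses radially running processes). Counts are
normalized to intersections per **mm of arc**, \(\hat I(r) = I(r) /
(2\pi r)\) with \(r\) in mm; circles clipped by the field border are
normalized by the in-field arc fraction by default (`clip = "full"`
restores whole-perimeter normalization). On an \(N\)-ray star this yields
exactly \(N\) at every radius and a pure \(1/r\) normalized decay.

`density_heatmap()` is a visualization aid: disk-kernel mean foreground
density in [0, 1].

## Marker-intensity classification

`segment_cells()` thresholds the channel-1 projection and labels connected
components (labelling runs on a one-pixel dilation so thin diagonal
processes stay attached to their cell, then labels are restricted to the
original mask), discarding components below `min_area`. `cell_mfi()` takes
the mean channel-2 projection intensity over each cell's mask — the whole
ramified mask, not the soma only. `classify_reference()` sets lower/upper
thresholds as quantiles (defaults: 5th and 95th percentiles) of a
reference group's MFI distribution — a reproducible proxy for thresholds
drawn on a young control group — and classifies cells as low / positive /
high. Classification is invariant to any affine intensity rescaling applied
jointly to test and reference. Note that with 5 %/95 % reference quantiles
a planted subpopulation analysis must account for the ~5 % of baseline
cells that land in each tail by construction; the recovery analyses in the
test-suite use 1 %/99 % quantiles for that reason.

## Group statistics

`compare_two()` is a Student two-sample t-test (equal variances by default,
Welch via `var_equal = FALSE`) returning group means ± SEM in one tidy row;
two degenerate limits are defined explicitly (identical constant groups →
t = 0, p = 1; separated constant groups → p = 0). `compare_many()` is
one-way ANOVA with Tukey HSD post hoc, with `tidy()`/`glance()` accessors.
Tables carry both cell and field identifiers, so either pooling unit can be
analysed.

## Numerical choices and degenerate inputs

* Coordinates are physical µm everywhere; voxel centres at
  \((i - 0.5)\,d\).
* Tree area requires ≥ 3 distinct, non-collinear projected points;
  otherwise a degenerate-geometry error is raised (a straight cell has no
  territory).
* Coverage volume is undefined at zero volume and errors rather than
  returning infinity.
* All-zero stacks and empty foregrounds raise "no cells" errors; an empty
  segmentation (nothing above threshold and area filter) is an empty
  result, not an error.
* Histogram bins are left-closed `[k·w, (k+1)·w)`.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; per-cell streams are derived from the master seed and
  cell index.

## Problem sizes used by the validation suite

The test-suite and `scripts/acceptance.R` run entirely on synthetic data at
sizes chosen to exercise every code path at desk scale: 200 random traces
for the hull oracle; 20–30 rendered cells (stacks of roughly
250 × 250 × 60 voxels) for raster round-trips; 50 random 340 × 340 px
fields for grid conservation; fields of 30–60 cells for coverage and
segmentation; n = 10 cells per group for the aging contrast (the per-group
size at which the phenotype presets were verified to separate with
p < 0.05 across dozens of independent replicates); 500-cell planted
mixtures for MFI recovery; 1000 label permutations for the ANOVA type-I
calibration.

## Limitations

* The generator emulates geometry and contrast, not optics: no real PSF
  shape, no depth-dependent attenuation, no photobleaching, no uneven
  (IbaI-like) labelling of fine processes, and no time dimension.
* Synthetic aged cells reproduce the *direction* and approximate magnitude
  of every reported aging contrast, but the coverage-volume reduction
  (median ≈ 30–35 % at n = 10 per group) is milder than the > 50 %
  reduction reported in real tissue; absolute published values (tree areas,
  grid means, Sholl counts) are not reproduction targets.
* Automated tracing is validated against synthetic ground truth only;
  correspondence with a human tracer on real stacks is untested and the
  well-separated-branch regime documented above bounds where exact topology
  recovery can be expected.
* The 2-D spatial-coverage pipeline analyses projections, as in the
  original workflow; a 3-D Sholl variant is out of scope.
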