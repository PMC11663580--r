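---
title: "Colour-hull segmentation and growth analysis: models and methods"
author: "hullgrow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour-hull segmentation and growth analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hullgrow)
```

## The segmentation model

Thresholding colour channels draws axis-aligned cuboid boundaries in colour
space, and distance-to-target-colour thresholding draws spheres. Both are
poor fits for organisms whose colours occupy irregular, elongated, or
multi-modal regions — senescing macroalgae, leaves with bright tips against
a pale tray, and similar heterogeneously coloured targets. `hullgrow`
instead lets the user (or an automatic calibration step) specify the target
colour volume directly, as a **hull in CIELAB space**, and classifies a
pixel as target when its colour lies

* inside the hull, or
* within a distance `delta` (in Delta E units) of the hull surface.

CIELAB is used because Euclidean distance there (Delta E) is approximately
proportional to perceived colour difference, so a single scalar `delta` has
a consistent perceptual meaning across the colour space. We deliberately use
plain Euclidean Delta E, not Delta E 2000: the hull itself absorbs the
anisotropy that the refined formulas try to model, and the simple metric
keeps surface distances geometrically exact. Classification is pixel-wise by
design — no neighbourhood, texture, or shape information — which keeps the
decision rule reusable across morphologies and makes segmentation exactly
reproducible.

### Hull construction and the alpha parameter

`buildHull(vertices, alpha, delta)` realizes the target volume as a
triangulated surface:

* `alpha = 0` — no edge-length limit: the surface is the **convex hull** of
  the vertices (computed by an incremental algorithm with outward-oriented
  facets).
* `alpha > 0` — the vertices are Delaunay-tetrahedralized, every
  tetrahedron with an edge longer than `alpha` (Delta E units) is
  discarded, and the boundary triangles of the retained solid form the
  surface. This admits concave and even disjoint colour volumes; disjoint
  components classify with union semantics.

Two conventions needed a decision because alpha-shape literature varies:

* the edge-length limit applies to **tetrahedron edges**, not only to
  boundary-facet edges — filtering solids rather than surfaces guarantees a
  watertight boundary by construction;
* `alpha` is an absolute maximum edge length, not the circumradius
  parameter of classical alpha shapes — an edge length in Delta E units is
  the quantity a user can read directly off the voxel display.

Degenerate vertex sets (fewer than 4 distinct points, collinear or coplanar
sets) are hard errors rather than lower-dimensional fallbacks: a silent 2-D
hull would classify almost nothing and be hard to diagnose. An `alpha` so
small that no tetrahedron survives is likewise an explicit
"empty hull" error.

### Numerical choices in the geometry

Voxel centres lie on a regular lattice — the most degenerate (co-spherical)
input a Delaunay construction can face. All Delaunay predicates therefore
run on deterministically jittered coordinates (quasi-random offsets, about
`1e-4` of the cloud diameter, derived from a fixed arithmetic sequence so no
RNG state is touched), while every measured quantity — edge lengths for the
alpha filter, facet geometry, distances — uses the original coordinates.
The tetrahedralization self-verifies: the retained tetrahedra must tile the
jittered cloud's convex hull volume to a relative `1e-6`, and on failure the
jitter is re-drawn with a larger amplitude. Mesh validity additionally
requires every facet edge to bound an even number of facets (watertightness,
allowing the rare pinched configuration where two components share an
edge).

Distance-to-surface uses the standard closest-point-on-triangle region
decomposition, vectorized over facet-point pairs; containment uses facet
half-spaces for convex hulls and membership in any retained tetrahedron for
alpha hulls. Boundary points count as inside, consistent with
classification at `delta = 0`.

## From photographs to colour space

`srgbToLab` applies the standard sRGB gamma expansion, the sRGB
RGB-to-XYZ primaries, and the CIE L\*a\*b\* transform under **D65 / 2
degrees** — the sRGB standard illuminant, which is the natural default for
consumer-camera imagery (D50 is available for unusual pipelines). The
conversion agrees with canonical published values (e.g. sRGB red at
L\* 53.24, a\* 80.09, b\* 67.20) and round-trips all 8-bit grays within one
8-bit step.

`voxelize` bins pixel colours by floor division on each Lab axis. The
default bin edge is **1.0 Delta E** — roughly the just-noticeable
difference, so one voxel is one "distinguishable colour". The voxel's
representative colour is the **bin centre**, not the mean of its members:
stable under resampling, independent of pixel order, and exactly
reproducible. `filterVoxels` drops bins holding fewer than `minPixels`
pixels (workflow default 20) so that hull vertices come from genuinely
occupied colour regions rather than sensor noise; the appropriate value
scales with image size.

Background masking from an upstream step is carried as a validity mask on
the `LabImage`: excluded pixels contribute to nothing downstream.

## Segmentation mechanics

`segmentImage` classifies each **distinct** colour once and broadcasts the
verdict to all pixels sharing it. Because deduplication is exact (not
voxel-level), this is provably identical to naive per-pixel classification
— the `perpixel` method remains available and the equality is asserted in
the validation suite. On photographs the distinct 8-bit colours are far
fewer than pixels, which is where the speed comes from.

Post-processing offers `removeSmall` (foreground components below
`remove_area` pixels, 8-connectivity) and `fillHoles` (enclosed background
components below `fill_area` pixels, 4-connectivity — the standard dual
connectivity pair). The default order removes debris first, so stray
foreground cannot seal a hole shut before filling is considered; both
thresholds default to 0 (off). Dice similarity between two empty masks is
defined as 1.0 (perfect agreement), and mask comparison requires equal
dimensions.

## Layout detection

Circular fiducial markers are found on the luminance plane by a
gradient-directed circular Hough transform. Votes are cast along both
gradient directions, so marker polarity (bright ring on dark or the
inverse) does not matter. Centres are taken from the radius-summed
accumulator and refined by an algebraic (Kasa) circle fit to edge pixels in
a generous annulus — the annulus must cover the marker's inner and outer
edges completely, because a clipped edge biases the fit. The
`minScore` floor (default 1: one full circle's worth of edge votes) rejects
stray vote pile-ups; a clean annulus scores about 2.

Centres are grouped by **single-linkage** clustering cut at a configured
pixel distance — single linkage because plate groups are compact blocks
separated by clear aisles, exactly the geometry where chaining is desired
and a distance cut is interpretable. The number of groups is emergent.
Groups are ordered by centroid (top-to-bottom bands, then left-to-right),
units within a group row-major (or column-major) with a row-banding
tolerance of half the median nearest-neighbour spacing, and indices
assigned 1..N across groups. Sorting is deterministic with ties broken by
row, then column, then radius. Regions of interest are discs of the
detected radius plus a configurable dilation; contested pixels go to the
nearest centre and the overlap is flagged per unit.

## Growth model

Per-unit areas over time are modelled as exponential growth,
`A(t) = A0 * exp(r t)`. The **relative growth rate** `r` (day^-1) is the
slope of an ordinary least-squares straight line fitted to `ln(area)`
against time. Zero-area records are excluded from the fit and flagged
(`ZeroArea`) rather than imputed with a pseudo-count; fewer than two
positive records yields no fit (`TooFewPoints`). The slope is invariant to
area units and to shifts of the time origin; calibrated areas
(`pixels * scale^2`) only shift the intercept by `2 ln(scale)`.

`ModelFitOutlier` is an advisory flag for series that fit the log-linear
model poorly: residual standard deviation of `ln(area)` above 0.3, or
r-squared below 0.7 (both configurable; `Inf`/`-Inf` disable). The flag
prompts inspection — overlapping regions of interest, herbivory damage,
segmentation gaps — and flagged units are excluded from group means but
always reported. A residual SD of 0.3 corresponds to ~35% multiplicative
area error, far beyond measurement noise in a working setup; the r-squared
floor catches series whose variance is dominated by structure the model
cannot express.

## The synthetic-fixture generator

`makeImageSeries` renders the study conditions end-to-end with known
ground truth: white fiducial rings on a grid (optionally jittered by up to
a few pixels), per-unit blobs growing as `A0 exp(r t)` with optional
log-normal area noise, blob colours sampled strictly inside a known hull
(shrunk towards the hull centroid so 8-bit quantization cannot push them
across the surface), and background sampled from a Lab cuboid whose whole
surface is verified to stay a stated margin (default three times `delta`)
outside the hull, with headroom for quantization. Because every rendered
colour is quantized to 8-bit sRGB before use, writing frames to PNG and
reading them back is lossless, and the pipeline's file-based results equal
the in-memory ones bit for bit. Optional defects with known sizes — holes
punched in blobs, target-coloured debris in the background — exercise the
fill/remove post-processing with an exactly known correct answer.

Truth areas are pixel counts from the generator's own rendering
bookkeeping, and the truth growth rate is the generator's own closed-form
least-squares slope on those counts — independent of the analysis
pipeline, so end-to-end agreement is a genuine cross-check.

What the generator deliberately does **not** emulate: lighting gradients
and shadows, specular highlights, JPEG compression artifacts, defocus,
occlusion between units, and the gradual colour drift of senescing tissue.
Passing the fixture suite therefore demonstrates that the machinery is
exact under its stated assumptions (separable colour populations, clean
markers), not that any particular real scene is separable — choosing
vertices and `delta` for a real scene remains the user's calibration task,
assisted by `hullFromMask` and Dice evaluation against reference masks.

## Validation scale

The validation suite runs at sizes chosen to exercise every code path while
remaining quick on a laptop: 20 random hulls of 4–40 vertices with 500
query points each against brute-force geometry oracles; 20 random clouds
with 10,000-point classification agreement against a reference convex
hull; 6-frame image series for segmentation exactness and determinism; 20
randomized jittered grid layouts; and 200 replicate growth series for bias
and standard-error calibration of the RGR estimator.

## Known limitations

* Hull construction is pure R and comfortable up to a few hundred vertices
  — ample for hand-selected or voxel-derived vertex sets, not intended for
  hulls over raw pixel clouds.
* Per-component `delta` values and weighted alpha shapes are out of scope.
* Layout detection assumes roughly co-axial circular markers of similar
  radius; perspective distortion and non-circular fiducials are not
  handled.
* The growth model is intentionally log-linear; logistic or Gompertz fits
  and between-group statistics are left to downstream analysis of the tidy
  CSV outputs.
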