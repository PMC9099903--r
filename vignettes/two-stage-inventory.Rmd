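---
title: "Two-stage urban tree inventories: models, parameters and design choices"
author: "urbantrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage urban tree inventories: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbantrees)
```

## The problem and the two-stage design

An urban tree inventory wants the planar position of every street and park
tree. Remote data make this cheap but noisy: airborne laser scanning (ALS)
sees every crown from above but also sees lampposts, antennas and roof
structures; street-level panoramas see stems directly but only along
trafficable streets, and single-image geolocation is coarse. The pipeline
therefore deliberately **over-detects in stage 1** — maximizing recall and
accepting many false positives — and **debugs false positives in stage 2**,
either by cross-checking each candidate against several independent images
or by classifying its orthophoto spectrum. After every stage, candidates
closer than a merge distance are fused, because one tree routinely produces
several nearby candidates (several images, or several local maxima in one
crown).

Six method combinations exist: `GSV`, `ALS` (stage 1 only), and
`GSV+GSV`, `GSV+ML`, `ALS+GSV`, `ALS+ML`. `runPipeline()` orchestrates all
of them over a scene object and scores the final candidates against ground
truth.

## Stage 1B: CHM and variable-window local maxima

The normalized point cloud is rasterized at `cell_size = 0.25` m taking the
**maximum return height per cell**; cells without returns are nodata, not
zero — zero-filling would manufacture artificial height steps (and hence
local maxima) along street canyons. One pass of a 3×3 **mean filter that
ignores nodata** smooths branch-level maxima; the window shrinks at raster
edges and nodata cells stay nodata. Whether the conventional smoother is a
mean or a median, and whether "3" means one 3×3 pass, is not standardized
across tools; the mean/3×3/one-pass reading is implemented and exposed
(`smoothCHM(chm, window)`).

Cell (i, j) covers the half-open square `[x0+(j-1)c, x0+jc) x
(y0-ic, y0-(i-1)c]`, so a point on a shared edge belongs to exactly one
cell; this convention is used identically by the rasterizer, the clipper
(cell-center containment) and the zonal statistics.

The CHM is clipped by the building footprints (cell centers inside or on the
boundary become nodata). `clipBuildings()` also accepts a `buffer`: a CHM
smoothed with a w×w kernel carries roof heights up to the wall-straddling
cell plus the kernel reach beyond the footprint — at 3×3 smoothing, two cell
sizes (0.5 m). Without that clearance a halo of ≥2 m cells survives along
every wall, each a spurious local maximum that can even chain-merge with a
genuine tree candidate and drag its centroid away. `runPipeline()` therefore
clips with `clip_buffer = 0.5` m by default; the bare `clipBuildings()`
default stays 0 (the literal footprint).

Treetops are **variable-window local maxima**: cell value *h* is a treetop
iff *h* ≥ `min_height` (2 m) and no valid cell within radius
`0.12 h + 0.5` m (evaluated at the candidate's own smoothed height; radius,
not diameter) has a larger value. Three conventions are pinned down because
the generic description leaves them open, and all are config switches on
`itdParams()`:

* the window is a **circle by cell-center distance ≤ radius**, with the
  queen (8-connected) adjacency always included even when the radius is
  below one cell (`neighborhood = "rook"` gives 4-connected);
* **plateau ties break row-major-first**, so output is deterministic;
* nodata cells inside the window are ignored, so trees at building edges
  remain detectable.

A brute-force restatement of this definition (plain triple loop) is kept in
the test suite and the implementation must match it exactly on randomized
rasters with plateaus and nodata holes.

## Stage 1A: single-image geolocation

Panorama pose gives heading, pitch and field of view. Pixel column → bearing
is standard for both camera models (rectilinear tiles and equirectangular
panoramas). Pixel row → distance is genuinely underdetermined from one
image; the package adopts the **flat-ground stem-base depression-angle
model**: with camera height `h_cam` and stem-base depression angle δ,
`d = h_cam / tan δ`. A stem base at or above the horizon row (δ ≤ 0) carries
no distance information and that detection is dropped (counted). The
simulator generates pixels with the exact inverse of this model, which makes
the contract testable end to end (zero noise ⇒ positions recover to <1e-6 m);
*no accuracy claim about real imagery follows from this* — real stem bases
sit on curbs and slopes, and real detectors miss the base row by pixels.

Each stem detection yields one candidate; duplicates from multiple images
are resolved by the merge step, not here. Trees are not triangulated across
images in stage 1 — the cross-image information is spent in stage 2A
instead, where it acts as a filter.

## Merging

Circular buffers of radius `merge_distance/2` (default 2 m) intersect
exactly when centers are closer than `merge_distance`; connected components
of intersecting buffers collapse to one candidate at the component centroid
(max member height, id = sorted member ids joined by `+`). Tangency at
exactly 4 m does not merge. Two open choices are exposed on `mergeParams()`:

* **Iteration**: chaining can leave two output centroids closer than the
  threshold; by default merging repeats to a fixed point (bounded by n
  passes, pass count recorded), `iterate = FALSE` gives the strict
  single-pass variant.
* **Centroid rule**: `point_centroid` (mean of member positions, default —
  identical to the union-polygon centroid for pairs of equal circles and
  exactly testable) or `polygon_centroid`, the area centroid of the buffer
  union computed by deterministic grid integration at step
  `merge_distance/50` (no polygon-boolean dependency).

## Stage 2A: nearest-images verification

For each candidate the three nearest stations are selected (planar distance,
ties by station id ascending, regardless of capture date). A detector
contract — `function(station, candidate) -> position or NULL` — abstracts
over how re-detections are obtained; `makeDetectionProvider()` implements it
over a detections table by re-projecting the station's detections and
returning the nearest within the association radius (the consistency
distance, 4 m). The candidate survives iff **all three** images yield a
position and all pairwise distances are < 4 m; it is then moved to the
centroid of the three positions. `require_all = FALSE` relaxes the
all-images rule for sensitivity analysis. The strict rule is what removes
single-image spurious detections: a false detection exists in one image
only, so its candidate cannot be re-found consistently in three.

## Stage 2B: spectral filtering

Around each candidate a 0.5 m buffer collects the orthophoto pixels whose
centers fall inside (center-in-circle, the same convention as everywhere
else); per band, the mean and the **population** standard deviation
(divisor n) are the features — with ~12 pixels per buffer the n vs n−1
choice is material, so it is explicit. Seven bands (R14, G14, B14, R17,
G17, B17, NIR17) give 14 features in fixed order.

Feature selection is a single-step **permutation-importance** ranking from a
seeded random forest, keeping the top fraction (default 0.5, never empty).
Multi-stage forest-based selection procedures serve to cut training time on
large feature sets; with 14 features a single ranking pass does the same job
and is simpler to reason about.

Four classifiers sit behind `trainClassifier()`: random forest (reference
default), a single-hidden-layer neural network, and linear/radial SVMs.
Accuracy is reported from **3 repetitions of seeded 10-fold
cross-validation** (fold count is a package choice — only the three
repetitions are conventional — and both are configurable), then the model is
refit on all data. Candidates with TREE posterior below the decision
threshold (0.5) are dropped; candidates whose buffer lies off-raster are
dropped and counted, since the method only operates where orthophotos exist.

## The synthetic scene generator

The generator is first-class, tested code: it is the only way to exercise
the pipeline end to end with known ground truth inside a package. It fixes
the acquisition conditions the pipeline targets — 0.25 m ortho pixels, 14
first returns/m², panorama stations every 15 m at 2.5 m camera height — and
makes every choice the data sources leave open explicit:

* **Street trees** at fixed spacing (10 m) along each street axis, offset
  4 m to the sidewalk on alternating sides, as on a real street — which also
  keeps every stem base below the horizon row of a passing camera. Trees sit
  at arc lengths 0, s, 2s, …; the far endpoint carries a tree exactly when
  the axis length divides. **Park trees** are a thinned Poisson process
  (20/ha) kept 6 m off the carriageway; all trees respect a 6 m minimum
  spacing and a 2 m wall clearance.
* **Crowns** are solids of revolution (paraboloids): surface height
  `z(d) = h (1 − (d/R)²)` for distance d from the stem, apex = tree height,
  zero at the crown edge. Crown returns get additive noise (sd 0.1 m,
  truncated at ±3 sd); ground returns are exactly 0 (flat terrain).
* **Buildings** are rectangles with a roof height (9 m), so the point cloud
  contains real roof returns and building clipping is a genuine operation,
  and sight lines to stems are blocked iff the station-to-stem segment
  crosses a footprint. Trees do not occlude each other — street-level
  methods are known to degrade where parallel tree rows mask one another,
  but no validated occlusion model exists for that, so none is invented.
* **Clutter** (default 25 lamppost-like objects, flat tops of radius 0.8 m —
  wide enough to survive 3×3 smoothing — heights 3–8 m) injects ALS false
  positives that carry NOT-TREE spectra.
* **Detections**: each visible tree within 60 m is seen with probability
  1 − miss_rate (default miss 0.1); bearing noise 0.5°, distance noise 1 m.
  Spurious detections (Poisson, default 0.5/image) point at ground targets
  **more than 5 m from every true tree**, so injected false positives are
  unambiguously false under the matching rule; a "false" detection inside a
  crown would be a correct inventory hit and would poison any
  removal-rate measurement.
* **Spectra**: class means are ≥10 sd apart on the NIR band (live
  vegetation is NIR-bright), weaker on the visible bands. Labeled training
  points are sampled 0.6 m inside crown edges (TREE) or 0.6 m outside all
  crowns (NOT-TREE) so a 0.5 m buffer is spectrally pure.

All randomness flows from one seed through per-artifact derived streams
(trees, cloud, ortho, detections, training samples), so each artifact can be
regenerated independently and bit-identically.

**What passing tests do and do not show.** The simulator shares its pixel
model with the geolocator, its crowns are smooth and isolated, its ground is
flat, and its spectra are Gaussian and separable. Green tests therefore
demonstrate that the *algorithms implement their definitions* and that the
two-stage logic removes injected false positives while keeping true trees —
they do not certify accuracy on real cities, where crowns interlock,
detectors miss systematically, terrain tilts the depression-angle model and
spectra overlap.

## Problem sizes and numerical choices

The test suite and the acceptance script use a 200 m × 200 m reference scene
(four streets, ~130 trees, ~560k returns, 52 stations) for end-to-end
checks, an 80 m × 80 m scene for per-stage behavior, 40×40 rasters for the
treetop oracle (50 instances) and ≤30-point sets for the matching oracle
(100 instances) — sizes chosen so the whole suite runs in about a minute
while every code path is exercised at realistic densities.

Other numerical conventions, in one place: distances compare strictly
(`< 4 m` merges, `< 5 m` matches, exactly 5 m does not); matching ties break
by candidate id ascending; metric percentages are rounded
half-away-from-zero to 2 decimals and F1 is computed from the *unrounded*
precision and recall (rounding first visibly changes the second decimal on
published-scale counts, e.g. TP=635/FP=911/FN=51 gives 56.90, not 56.89);
zero denominators yield 0 by convention; all-nodata rasters yield empty
candidate sets rather than errors; empty candidate or truth sets evaluate to
zero counts.

One published benchmark table of per-zone TP/FP/FN counts with printed
metrics ships in `inst/extdata/pamplona_benchmark_counts.csv` as input data
for the metric arithmetic. Its pooled ALS row is internally inconsistent —
the printed counts neither match the per-zone sums nor reproduce the printed
precision/recall under any reading — and is flagged `consistent = FALSE` and
excluded from checks; the other 35 rows reproduce exactly.

## Known limitations

* Flat terrain throughout: no ground normalization (inputs are assumed
  height-normalized) and the single-image distance model ignores slope.
* LAS/LAZ and GeoTIFF are not read or written; point clouds exchange as XYZ
  text and rasters as Esri ASCII grids (both GDAL/QGIS-readable), vectors as
  GeoJSON, tables as CSV.
* Crown segmentation, species/health attributes and crown metrics are out of
  scope; candidates are points.
* The CNN stem detector is represented by its output contract (a detections
  table / provider function), not by a trained model.
* `mergeCandidates()` drops auxiliary columns (a merged candidate has no
  single provenance row); analyses that need provenance should join on the
  logged component membership.
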