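---
title: "organtraits: measurement conventions, evaluation model, and synthetic scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{organtraits: measurement conventions, evaluation model, and synthetic scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organtraits)
```

`organtraits` measures a fixed 64-trait catalog per image from an RGB image
plus an instance label map, evaluates segmentations with the standard
instance-level metrics, and generates seeded synthetic scenes with exact
ground truth. This vignette records the measurement conventions precisely —
the numbers change if any of them change — together with the design choices
made where more than one defensible convention exists, and what the synthetic
scenes do and do not establish about real data.

## The measurement model

The segmentation contract is an integer **label map**: 0 = background,
k = 1..N = pixels of organ k. Labels are compacted to a contiguous
`{0..N}` on load (first-appearance order in raster scan), so downstream code
can index organs densely. Coordinates are 0-based with the origin at the
top-left pixel center, x = column, y = row. Every length/area is in pixel
units; converting to metric units is the caller's business (a scale object in
the image is the usual practice).

### Morphology (35 traits)

* **Area** is the pixel count of a label.
* **Perimeter** is the length of the traced outer contour polygon through
  boundary pixel *centers*: orthogonal steps contribute 1, diagonal steps
  √2, holes are ignored, and a single-pixel organ has a degenerate contour of
  length 0 (it is excluded from roundness summaries). Under this convention
  an n×n square measures exactly 4(n−1). The convention's known cost is a
  staircase bias on smooth boundaries: a digitized straight edge at angle θ
  is overmeasured by the factor cos θ + (√2−1) sin θ, which is 1.000 at 0°
  and 45° and peaks at ≈1.083 at 22.5°; averaged around a circle the factor
  is ≈1.05. The test suite asserts exactly this band on a digital disk of
  radius 50 rather than pretending the estimator is unbiased. Corrected
  estimators (e.g. Vossepoel–Smeulders step weights) would trade the exact
  square identity for lower bias on curves; we keep the transparent
  convention and document the bias.
* **Roundness** is the isoperimetric ratio 4πA/P² (1 for an ideal circle,
  π/4 for an ideal square), computed from the conventions above and not
  clipped; the digital-disk value lands near 1/1.05² ≈ 0.91.
* **Orthogonal box** extents are max − min + 1 per axis (pixel-as-unit-square),
  reported as length ≥ width; the `_ori` traits and their maxima
  (`c_max_ori`, `h_max_ori`) come from these.
* **Minimum-area rectangle** and **convex hull** treat each boundary pixel as
  a unit square and operate on its corner points. This is deliberate: with
  center points a filled 10×10 block would get hull area 81, *less than its
  own area* (100), breaking the containment chain
  area ≤ hull ≤ min-rect ≤ orthogonal box that the corner model preserves.
  The minimum rectangle uses rotating-calipers semantics (the optimum has a
  side collinear with a hull edge), so it is exact, not a search.
* **Aggregation**: Average/Maximum/SD/CV per plant, with the *population* SD
  (divide by n — per-plant dispersion is descriptive) and CV as a plain
  ratio. A single organ therefore has SD = CV = 0. `MBB_Area` without a
  prefix is the maximum over organs, by analogy with the other
  `Maximum`-style entries. Ratio traits follow their names read at the plant
  level: `Average Area/MBB_Area` averages per-organ ratios;
  `Average Perimeter/Area` is mean perimeter over mean area; the SD variants
  divide the SD of the numerator trait by the mean of the denominator trait.
  The per-organ-ratio alternative for the latter two is a defensible reading
  we did not take; switching would change only those columns. The plant-level
  `Convex Hull Leaf Area` is the hull over the union of all organ pixels.
  Organs touching the image border are measured as-is.

Undefined values (summaries of an empty scene, roundness of a degenerate
contour, CV at zero mean) are a sentinel — `NA` in memory, an *empty cell* in
CSV — never 0, so batch aggregation cannot be silently biased.

### Color (7 traits)

Each organ pixel contributes chromatic coordinates r = R/(R+G+B) etc.; a pure
black pixel contributes (1/3, 1/3, 1/3) so it stays on the simplex rather
than forcing a 0/0. Means and population SDs are taken over the *union* of
organ pixels (not over per-organ means — the per-organ alternative is noted
as a sensitivity point). The coordinates are invariant to global intensity
scaling, and `G_All_mean`, the whole-plant green proportion, numerically
equals `G_Ratio_mean`; both are kept so the 64-column catalog stays intact.
Raw 0–255 channel means are available behind
`color_traits(..., raw_channel_means = TRUE)` as non-catalog columns.

### Texture (22 traits)

**Hu moments** are computed on the binary organ support (shape descriptors;
a grayscale-weighted variant sits behind `hu_moments(..., weighted = TRUE)`),
with central moments normalized by μ₀₀^((p+q)/2+1) and φ₇'s sign preserved so
mirror images are distinguishable. Translation invariance is exact;
rotation/scale invariance holds up to digitization error, which grows with
moment order: on ~3·10⁴-pixel shapes the low-order invariants φ₁–φ₃
reproduce to well under 1% across a 33° rotation plus 1.4× scaling, while
φ₄–φ₇ — small signed combinations of third-order moments — carry a few
percent. The invariance tests assert 1% for φ₁–φ₃ and 8% for φ₄–φ₇,
reflecting that measured behavior.

**GGCM**: grayscale by luma (0.299R + 0.587G + 0.114B); gradient magnitude by
a 3×3 Sobel. So that boundary organ pixels are not contaminated by
background, background pixels adjacent to the support are first filled with
the value of their nearest organ neighbor (orthogonal before diagonal, fixed
order, deterministic), and the image frame is edge-replicated. Gray is
linearly quantized to 16 bins over [0, 255]; gradient to 16 bins over
[0, max gradient within the support] (an organ of constant intensity puts all
mass in gradient bin 1 — a valid, not exceptional, state). The joint
histogram over organ pixels is normalized to sum 1, and the 15 canonical
features (small/large-gradient dominance, gray/gradient asymmetry, energy,
gray/gradient mean and variance, correlation, three entropies, inertia,
inverse difference moment) are closed forms over that matrix. Entropies use
the natural log with 0·log 0 = 0; correlation is normalized by the marginal
SDs and set to 0 when a marginal is degenerate. The trait is per-plant
(union of organs), matching an "of the image" reading; the feature order and
log base are part of the file contract.

## Evaluation

Matching is bipartite on pixel IoU: all (predicted, truth) pairs with
IoU ≥ threshold are candidates; pairs are accepted greedily in descending IoU
with a deterministic tie-break (lower predicted label, then lower truth
label), each instance used at most once. The threshold default is 0.5 and is
configurable — the TP criterion is the one genuinely open knob in this kind
of evaluation, so it is surfaced rather than buried. On every small scene we
can check exhaustively, greedy TP equals the optimal-assignment TP (the test
suite and acceptance script both verify this).

Precision, recall, F1, and DiC are the standard closed forms; batch DiC is
the mean of per-image DiC values, batch P/R/F1 pool the counts. MAPE is in
percent and requires nonzero manual values (a zero raises an error naming the
offending index). R² comes from OLS of the manual value on the automated
value — the orientation of the usual agreement scatterplots (automated on x)
— as 1 − SS_res/SS_tot, with a sentinel when the predictor has zero variance.
`trait_agreement()` objects support `tidy()`/`glance()` and `autoplot()`.

## Classical baselines

The bundled baselines are the methods organ-level pipelines are compared
against, not competitive segmenters. ExG (2G − R − B) is the color-to-gray
transform feeding Otsu (first of the standard vegetation indices; others
would slot in trivially). Otsu maximizes between-class variance over the
256-bin histogram with ties broken toward the *lower* threshold, and
foreground is strictly above the threshold (greenness is high for plants); a
constant image yields an empty foreground with a warning. K-means runs
Lloyd's algorithm on RGB triples with k-means++-style seeding from a caller
seed (deterministic), reduces k when there are fewer distinct colors, and
designates the cluster with the highest-ExG center as "plant". Binary masks
become instances via connected components (4- or 8-connectivity, labels in
raster-scan order of first pixel) with a minimum-area floor of 20 px to
suppress salt noise. On scenes with touching organs these baselines merge
neighbors; truth masks evaluate perfectly — the qualitative failure mode
becomes the inequality baseline DiC ≥ truth DiC = 0, asserted in tests.

## Synthetic scenes

The generator emulates the two imaging setups this class of pipeline serves:
top-view rosettes (3–20 elliptical blades with petiole stalks radiating from
a center, per-leaf green hue jitter, soil-like flat or textured background)
and flatbed-scan silique scenes (bright scanner bed, a thin curved stem that
is *background class* in the label map, elongated slightly curved capsules
attached at spaced points). Scenes are bit-identical for identical specs:
all randomness flows from the spec seed.

Ground truth is the *visible* pixel set: occlusion is realized by draw order,
later organs overwriting earlier ones in both image and label map, which is
exactly what a segmenter of the final image could recover. Latent
(un-occluded) areas are stored alongside for sensitivity studies. With
`overlap = 0` organ supports are strictly disjoint — placements are
re-jittered toward even angular spacing, shrunk, and pushed outward for up to
40 attempts before an organ is dropped with a warning (petioles start at
radius 2.2/sin(π/n) from the center so disjoint stalks are geometrically
possible; at n = 20 in a 256 px frame some drops are unavoidable and the
truth is updated). With `overlap > 0` the rosette's radial compactness is
calibrated per scene by bisection on the measured occlusion fraction, so the
target is tracked within a few percent; for siliques a positive overlap
requests deliberately crossing capsule pairs, guaranteeing that connected
components on the organ union under-count — the baseline failure mode on
demand. Default sizes (256 px rosettes with 40–80 px leaves, 320 px silique
scenes with 60–100 px capsules) keep per-scene generation and measurement
under a second; the test suite uses 3–20 scenes per property and 20 seeds
where a distributional claim is made.

What passing on synthetic scenes shows: the bookkeeping is exact (counts,
areas, label correspondence, determinism), the geometry engines are correct
on shapes whose true parameters are known, and the evaluation layer is
self-consistent (truth vs truth is perfect). What it does not show: substrate
realism. Real rosettes have lobed and serrated blades, venation, specular
highlights, shadows and soil clutter; real scans have sensor noise and
debris. No claim about segmentation accuracy on real images follows from
these scenes — by design, segmentation is an input here.

Augmentation (`augment()`) applies flips/rotations/scaling/cropping
identically to image and map (map always nearest-neighbor so labels stay
integral) and noise/color dithering to the image only, all seeded.

## Numerical choices and degenerate inputs

* Polygon rasterization (LabelMe JSON): a pixel belongs to a polygon iff its
  center is inside under the even-odd rule, with on-edge centers counted
  inside for determinism; later shapes overwrite earlier; sub-3-vertex
  polygons are skipped with a warning. Verified pixel-for-pixel against an
  independent point-in-polygon oracle.
* Label maps are stored as single-channel 8-bit PNGs (up to 255 instances —
  an order of magnitude above realistic per-image organ counts; exceeding it
  is an error, not a silent wrap). 16-bit single-channel inputs from other
  tools are read correctly.
* CSV is the canonical trait table format (values round-trip to at least 6
  significant digits; sentinels are empty cells). XLSX export is a formatting
  layer over the same table, delegated to the Python openpyxl library
  available on the host, since no R spreadsheet writer is among this
  package's dependencies.
* Otsu ties break toward the lower threshold; matching ties break toward
  lower labels; component labels follow raster order — every tie in the
  package has a documented, deterministic resolution.
* A non-8-connected "instance" (which a well-formed map should not contain)
  is measured by its largest component for contour-based quantities, with a
  warning; its area remains the full pixel count.
* The minimum-area-rectangle tests compare against a 0.01°-step rotation
  search. That grid search itself carries discretization error (up to
  ~1.75·10⁻⁴·D² absolute over a half step), so the tests assert the
  direction brute force can certify — the calipers result never exceeds the
  grid minimum — plus the analytic grid bound and a sub-10⁻⁴ mean relative
  error, rather than a two-sided tolerance below the oracle's own
  resolution.

## Known limitations

Perimeter bias on smooth boundaries (≈5% on circles) is inherent to the
stated convention and propagates to roundness (disk ≈ 0.91, not 1.0);
comparisons *across* plants measured with the same convention are unaffected,
but absolute roundness values should not be read against the continuum ideal.
Leaf "length" via rectangle sides is a straight-line proxy; midrib arc length
(skeleton-based) is out of scope, as are petiole/blade decomposition, other
color spaces, Haralick GLCM offset/angle suites, and 3D traits. The texture
traits are per-plant, not per-organ. The synthetic scenes support correctness
claims, not realism claims.
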