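---
title: "Measuring pumpkin biophysical properties from images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pumpkin biophysical properties from images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumpkinpheno)
```

This vignette is the package's own account of the measurement model: what
each stage computes, the assumptions it makes, the parameters that matter,
and the numerical choices taken where the design was genuinely open. It
states no empirical claim that the test suite and `scripts/acceptance.R`
do not themselves compute.

## The measurement problem

Given an RGB photograph containing a pumpkin fruit, the stem-adjacent
vine, a ruler of known physical length, and a 24-patch color checker —
plus binary instance masks for the fruit and vine from any segmentation
source — the pipeline reports five biophysical properties per sample:
fruit length (FL), fruit width (FW), vine length (VL), vine width (VW),
all in millimetres, and a categorical fruit peel color
(FPC ∈ {G, OR, LG}). The package deliberately excludes the segmentation
model itself: masks are an input, and a simple HSV-threshold baseline is
provided only for synthetic scenes.

## Color correction

Under stable lighting, chip values of the same physical checker in two
images are related linearly channel-wise. We estimate a 3×3 matrix $M$
(optionally with an offset $b$) minimizing
$\sum_{k=1}^{24} \lVert M s_k (+\,b) - r_k \rVert^2$ over the chip-mean
pairs $(s_k, r_k)$ and apply $p \mapsto \mathrm{clip}(Mp + b, 0, 1)$ per
pixel.

Design choices:

* **Color space.** Fitting operates on the stored (sRGB-encoded) values
  without gamma linearization — the simplest faithful reading of a linear
  per-pixel correction, and the variant the rest of the pipeline is
  calibrated against.
* **Model.** Default is the pure 3×3 linear map; an affine 3×3 + offset
  variant is available because outdoor casts often include an additive
  component. Least squares guarantees the fitted map never has a larger
  chip-space residual than the identity.
* **Conditioning.** Fits are rejected when the 24×3 source chip matrix
  has condition number above 10⁸ (e.g. an all-gray checker): the normal
  equations are then meaningless, and the error message carries the
  condition number.
* **Localization.** Chip rectangles come from configuration (or from the
  scene generator); automatic checker detection is out of scope. Each
  chip mean excludes a `sample_margin` (default 0.2) border fraction to
  avoid edge bleed.
* **Diagnostics.** `linearity_report()` fits the per-channel
  reference-vs-source line and flags chips whose residual exceeds 2
  residual standard deviations — the practical check for chips corrupted
  by glare or shadow.

## Ruler detection and pixel scale

The ruler is found by the classical chain: luminance grayscale → Gaussian
blur → Canny edges → Hough transform. Defaults (`blur_sigma = 2`,
Canny 50/150 on the 8-bit gradient scale, `min_line_frac = 0.3`,
`max_gap_px = 10`) are conventional values for high-contrast rulers on
matte backgrounds; none is critical within a factor of two.

Numerical details worth recording:

* The Hough stage votes in a 1°/1 px accumulator, then **refines each
  peak by total least squares** on its support band (±3 px) before
  collecting segment pixels. Without refinement, lines falling between
  accumulator cells lose several percent of their length.
* Support pixels are **orientation-filtered**: a pixel backs a line only
  if its local gradient is within 30° of the line normal. This prevents
  the segment from bleeding around the ruler's rounded end caps (whose
  gradients rotate by ≥ 45°), while tolerating the mild gradient rotation
  that blur causes near the ends. With both measures, recovered scale is
  within ≈ 0.8 % of truth across orientations 0–45° on synthetic scenes
  (recomputed by `scripts/acceptance.R`).
* Among qualifying segments the **longest** wins; ties go to the most
  vertical, then the smallest x. The accepted-length threshold is a
  fraction of the image diagonal side, so the ruler must be a dominant
  line in the frame.
* The physical length corresponding to the detected span is a required
  configuration input (`ruler_length_mm`); graduations are not read.

Coordinates everywhere are 0-based with x = column, y = row, origin at
the top-left pixel center; distances are between pixel centers.

## Lengths from the medial-axis skeleton

Length is defined on the mask's medial axis: the mask is thinned to a
one-pixel-wide skeleton, the longest path through the 8-connected
skeleton graph is extracted by a double breadth-first search (ties broken
toward the lexicographically smaller pixel), and the default length is
the **pixel count along that path** — a unit contribution per pixel,
i.e. a calibration factor of 1 in the discrete line integral. An
alternative `euclidean` step model sums 1/√2-weighted steps, and a
`total_pixels` scope counts every skeleton pixel for literal summation
over branched skeletons.

The skeletonization itself is Zhang–Suen thinning **anchored at centers
of maximal inscribed disks**. Plain thinning collapses blunt convex
shapes (a disk thins to a point; a mildly eccentric ellipse to a short
segment), which is wrong for a length measurement that wants the medial
axis. Anchors are detected on the Euclidean distance transform: away
from the medial axis the distance grows at unit rate along the direction
away from the nearest boundary point, so a pixel is *off* the ridge when
some probe direction gains distance at (quantization- and
jitter-corrected) unit rate. Probes use rings of radius 1–4: short rings
give spatial precision, long rings resolve slow-looking growth that
boundary rasterization jitter (±½ px) hides from short ones; thresholds
per ring are 0.95, 0.85, 0.85 and 0.82 of the ideal unit rate. Pixels
with distance below 2 px are never anchored — at that scale the discrete
distance transform carries no reliable ridge evidence, and genuinely
thin structures survive thinning without anchors.

Two discretization effects are inherent and documented rather than
hidden:

* **End effects.** The discrete ridge ends a few pixels short of the
  continuous medial-axis endpoints. For a solid ellipse with semi-axes
  $a > b$ the continuous medial axis has length $2(a^2-b^2)/a$; the
  measured skeleton length falls below it, within a band bounded by the
  end-cap radius ($b^2/a$ per end). The test suite asserts the band, not
  the continuous value.
* **Diagonal undercount.** Pixel counting advances one unit per step
  also on diagonal steps, so paths at 45° count ≈ 1/√2 of their
  Euclidean length (a 100-pixel diagonal line counts 100, Euclidean
  ≈ 140.01). For gently curved, mostly axis-aligned structures such as
  the synthetic vines the undercount is 1–3 %.

## Widths

Fruit width uses the affine method: a **moment-based ellipse fit**
(centroid + eigen-decomposition of the second central moments, axes
scaled so a solid ellipse is recovered exactly) gives the rotation angle;
the mask is rotated about the ellipse center by the negative angle with
nearest-neighbour resampling on an enlarged canvas so nothing clips; the
width is then `max(y) − min(y) + 1` over foreground pixels — the
farthest-point extent perpendicular to the major axis. Reading the
"distance between the two farthest points" as the *perpendicular* extent
is a deliberate disambiguation: the parallel extent would duplicate the
length measurement. Moment fitting was chosen over contour least squares
because it is deterministic, contour-free, and exact for solid
ellipses.

Vine width defaults to **twice the median medial-axis radius along the
skeleton path**: the affine extent of a curved vine measures its bend,
not its thickness. Both estimators are available for both roles through
configuration. The tube estimator is documented as meaningless for round
blobs (the path barely crosses the center).

Rounding: all values are kept at full double precision internally;
reports round half-even to 2 decimals.

## Peel color

Masked pixels are converted to HSV and counted against per-category
boxes; the argmax wins, with ties resolved orange > green > light green.
The default ranges (hue in degrees) are: orange H ∈ [10, 40), S ≥ 0.30,
V ≥ 0.30; green H ∈ [60, 170), S ≥ 0.25, V < 0.65; light green the same
hue band with S < 0.25 or V ≥ 0.65. The three regions are pairwise
disjoint by construction; all are configurable. These defaults encode
the field convention that light-green peels are pale (low saturation) or
bright (high value) within the green hue band; no published range was
available to adopt.

## Evaluation metrics

MAE and MAPE are computed per sample over the **four quantitative
properties** (N = 4); FPC enters only as a match flag. This reading is
fixed by the embedded worked example: its consistent cells (e.g. sample
S5, MAE 0.15) reproduce exactly under N = 4. The embedded 10-sample
table also contains cells that are *inconsistent* with the definitions
(samples S4 and S8), and its two reported grand averages disagree with
any recomputation (the recomputed means are 0.202 and 2.66 %, while the
printed per-sample rows average 0.204 and 2.54 %). The package
reproduces the consistent cells, asserts the inconsistencies in its test
suite, and pins nothing to the irreproducible aggregates. The
per-sample "accuracy" row of that table follows no formula reproducible
from its stated definition and is not implemented.

Mask AP sorts predictions by confidence, matches greedily one-to-one to
the highest-IoU unmatched ground-truth mask at IoU ≥ 0.5, and integrates
the all-point interpolated precision–recall curve (exact breakpoint
integration, not 101-point sampling). IoU is pixel-set IoU, not bounding
boxes. Classes without ground-truth instances are excluded from the
mean. Equivalence with exhaustive enumeration is tested for small
prediction sets.

## The synthetic scene generator

`random_scene_spec(seed)` draws scenes from fixed study-condition
ranges: canvas 600×800 px; scale `mm_per_px` ~ U(0.05, 0.2); fruit
semi-axes a ~ U(100, 140), b ~ U(60, 85) px at orientation U(−25°, 25°);
vine as a quadratic Bézier tube of radius U(8, 12) px with a gentle
upward bow; a near-vertical ruler bar of 400–500 px; the checker at a
fixed top-left position. Fruit colors are drawn inside the HSV region of
the requested peel category; layout bands keep all elements disjoint for
every draw (violations raise a layout error). These ranges are the
package's chosen test conditions: they produce fruit/vine proportions and
scales comparable to close-range phenotyping photographs while keeping
render and skeletonization costs small enough for routine testing.

Rendering is hard-edged (no anti-aliasing), so the ground-truth masks are
exact pixel sets; realism is deliberately sacrificed for testability.
Truth values are closed-form: FW = 2b·mm_per_px, FL from the ellipse
medial-axis formula, VL from fine polyline integration of the Bézier arc
(tolerance ≲ 10⁻⁶ relative), VW = 2r·mm_per_px. Reference chip colors
are 18 spread hues plus a 6-step gray ramp — not any proprietary chart's
values — and are configurable.

Random color casts are drawn as row-stochastic nonnegative mixing
matrices (identity plus mixing up to 0.12 before row normalization):
such casts never clip in-gamut images, are invertible, and preserve
grays, which makes the cast → fit → correct round trip exact to machine
precision and keeps the round-trip test a clean probe of the fitting
algebra.

What the generator does **not** emulate: illumination gradients, shadows,
specular highlights, anti-aliased or motion-blurred edges, occlusion,
multiple fruits, background clutter, and lens distortion. Passing the
synthetic recovery tests therefore demonstrates the correctness of the
measurement chain, not field robustness of segmentation or detection on
real photographs.

## Degenerate inputs and error behavior

Empty masks, sub-5-pixel or collinear masks (ellipse fit), zero-length
ruler lines, non-positive physical lengths, out-of-range scores,
zero-ground-truth MAPE entries, and all-gray checkers raise typed errors
with diagnostic payloads (candidate counts, condition numbers, HSV
histograms). Batch runs isolate per-sample failures and report them
without aborting; an all-failed batch exits nonzero. A single-pixel mask
yields a single-pixel skeleton of length 1 by convention.

## Known limitations

* FL inherits the discrete end-effect and diagonal-undercount biases
  described above; against the *continuous* medial-axis value the
  per-scene deviation is typically 3–10 % even when the measurement is
  internally exact. Applications needing unbiased absolute fruit length
  should calibrate against the documented band.
* The tube-width estimator quantizes at the ±1 px level, which bounds
  relative accuracy for very thin vines (r ≲ 4 px).
* Ruler detection assumes the ruler is the longest straight high-contrast
  structure; heavily textured rulers (dense graduations) at very low
  resolution can fragment the Hough support.
* Color correction is linear; strongly clipping or spatially varying
  casts are outside the model.
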