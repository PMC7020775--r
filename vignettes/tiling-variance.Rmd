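---
title: "Tiling, stitching, and the translational variance of segmentation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiling, stitching, and the translational variance of segmentation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tileseg)
```

## The problem

Large medical and remote-sensing images rarely fit through a convolutional
segmentation network in one piece, so inference is run on tiles — fixed
corner-plus-center crops or a sliding window — and the per-tile predictions
are stitched back together. Convolutional networks are only
shift-equivariant at multiples of their cumulative stride: a stack of
`d` max-pooling layers with 2×2 windows commits to a fixed pooling grid, so
translating the input by anything other than a multiple of `2^d` pixels can
change the output. Tiling therefore changes predictions: the stitched
whole-image prediction is not the prediction on the whole image, and the
differences concentrate where they matter most, along segmentation
boundaries.

`tileseg` packages the machinery needed to quantify these effects on
synthetic data: tile-layout generation in 2D and 3D, two aggregation rules,
pixel- and instance-level metrics, a deterministic from-scratch U-Net-style
forward engine, flip/translation variance protocols, and generators for
MRI-like phantoms and building scenes. No training is involved anywhere;
every model is a seeded, reproducible random network, which is sufficient
because all the properties under study are geometric.

## Tiling geometry

Coordinates are 0-based with half-open extents `[offset, offset + shape)`,
and arrays are channels-last (`(H, W, C)` in 2D, `(H, W, D, C)` in 3D); the
paper-style corner+center layout places `2^d` corner tiles plus one center
tile at `floor((image - tile)/2)`:

```{r}
corner_center_layout(c(240, 240), c(128, 128))
corner_center_layout(c(240, 240, 155), c(128, 128, 128))
```

The center-tile offset uses floor rounding on odd margins (the 155-deep
axis gives `floor(27/2) = 13`); coincident placements are deduplicated, so
a tile as large as the image yields a single placement. The sliding-window
layout strides by `round(tile * (1 - overlap))` and clamps the final tile
to the image boundary rather than padding, so a 650-pixel side with
128-pixel tiles at 50% overlap gets 10 offsets per axis, the last at 522.
Both choices are conventions this package fixes where the underlying
protocol is silent; they are recorded here and used everywhere.

## Aggregation rules

Overlapping tile probabilities are combined in one of two ways:

* **rounding after averaging** — average the tile probabilities pixelwise
  (uniform `1/coverage` weights), then threshold at 0.5;
* **rounding before averaging** — threshold each tile at 0.5, average the
  binary votes, then threshold the vote fraction at 0.5.

The two rules genuinely disagree: a pixel covered by tiles predicting 0.6
and 0.2 averages to 0.4 (background) under the first rule, but votes
`{1, 0}` for a tie of 0.5 under the second. Ties resolve half-up (a value
exactly at the threshold is foreground); the final 0.5 threshold on vote
fractions is this package's choice — binary Dice needs a binary mask, and
the vote average of {0,1} values is fractional wherever coverage is even —
and it is exposed in `aggregation_config()`. Pixels covered by no tile
default to background with an explicit `uncovered` report rather than an
error, so partial layouts remain usable.

## Metrics

Pixelwise quality is the Dice similarity coefficient
`2·TP / (2·TP + FP + FN)`, with the empty/empty case defined as 1 (the
brain-tumor benchmarking convention; a correct empty prediction is
perfect). Instance-level quality is the building-footprint F1: the
predicted mask is polygonized by connected components (4-connectivity by
default, exposed as a parameter since "same-value connectivity" does not
pin down 4 vs 8), polygons are matched one-to-one to ground truth greedily
in descending IoU order, a match requires IoU strictly above 0.5, and F1
is the harmonic mean of precision and recall over the match counts.

Polygonization traces the exact pixel-boundary outline on the integer
lattice, so a polygon's area equals its component's pixel count; holes are
kept as negatively-oriented interior rings and subtract from the area. A
component that pinches at a corner (possible under 8-connectivity) is
represented by several positive rings. Polygon IoU is computed exactly for
rectilinear pairs (grid decomposition on the union of their vertex
coordinates) and for convex partners (Sutherland–Hodgman clipping), with a
supersampled rasterization fallback for the remaining cases; the greedy
matcher breaks IoU ties by index and never produces more matches than the
optimal assignment.

The reason for carrying both metrics is the merged-instance failure mode:
one blob covering two 10×10 buildings separated by a 5-pixel gap scores
Dice `400/450 ≈ 0.889` yet IoU 0.4 with each building, hence zero matched
polygons and F1 = 0.

## The forward engine

`build_unet()` constructs a deterministic encoder–decoder: per level,
`convs_per_block` convolutions (odd kernel, default 3) with ReLU or leaky
ReLU and optional instance normalization (applied after the activation,
epsilon 1e-5, per-channel statistics of the current input), then 2×2 max
pooling; a bottleneck; then per decoder level nearest-neighbour ×2
upsampling followed by a 1×1 channel-halving convolution, skip
concatenation, and another convolution block; finally a 1×1 sigmoid head.
Weights are uniform on `(-a, a)` with `a = sqrt(3/fan_in)` from a single
seeded generator and zero biases, so the same configuration is bit-identical
across runs; the generator state of the caller is left untouched. Dropout
does not exist at inference and there is no training path — learned
accuracy is out of scope by design, and none of the geometric properties
tested here depend on the weights' values.

Two choices deserve a note. The upsampling operator is nearest-neighbour
followed by a 1×1 convolution: it is deterministic, framework-free, and —
because a 1×1 convolution does not shrink — keeps the valid-mode shape
recurrence identical to the classic unpadded encoder–decoder arithmetic:
each convolution removes `kernel - 1` pixels per axis, pooling halves with
floor, upsampling doubles, and skip connections are center-cropped (the
extra pixel removed from the leading side when the crop is odd). The
recurrence maps 236 → 52 and 572 → 388 at depth 4, and `unet_forward()`
reproduces it exactly. Second, input admissibility is decided by walking
the pooling flow — every spatial dimension must be even at each of the
`depth` pooling steps so the decoder re-aligns with the skips — which is
equivalent to divisibility by `2^depth`; the walk, not the formula, is what
`validate_input_shape()` evaluates, and the 650-pixel scene side is
rejected at depth 5 with modulus 32.

## Variance protocols

All comparisons happen in image coordinates: a prediction that is smaller
than its input crop (valid padding) is placed at the crop's center, and two
predictions are compared only on the region their placements share.
`flip_variance()` predicts on an image and its flipped copy, un-flips the
second prediction, and reports Dice against truth for both, the cross-Dice
between them, and a gray/white/black trinary difference map.
`translation_variance()` walks every non-zero integer offset with
components in `[-k, k]` (24 offsets for `k = 2`) and reports the same
quantities on the overlap. "Identical" always means exact binary equality —
predictions are thresholded (half-up at 0.5) before comparison.

Boundary localization is reported two ways: the share of disagreeing
pixels inside a 3-pixel band around the ground-truth boundary, and the
per-pixel disagreement *rates* inside and outside that band. The rate
comparison is the meaningful one for untrained networks: the band is a
small fraction of the image, and random-weight models also disagree along
other intensity edges (the tissue-support rim) and in noise, so the raw
in-band share cannot dominate; the in-band rate exceeding the outside rate
is the form in which border concentration shows up, and the test suite
asserts it for the majority of 20 seeds.

The pooling mechanism itself is isolated in two exhibits.
`maxpool_window_demo()` is the minimal one: an 11×2 array admits exactly
two 10×2 unit-stride windows, and their 2×2-pooled 5×1 outputs differ
whenever a distinguishing value sits in the first row.
`pool_stack_shift_search()` slides a window over a 1D strip and searches
exhaustively over single-impulse inputs: a stack of three 2×2 pools
disagrees somewhere for every shift 1–7 and 9–15 and can never disagree at
multiples of `2^3 = 8`, which `equivariant_stride()` extracts as the stride
at which equivariance is restored.

## Synthetic data

The scan phantom emulates the geometry of multi-parametric brain MRI — a
4-channel 240×240×155 volume, exactly zero outside an ellipsoidal tissue
support, with blob-like lesions whose union is the mask and a distinct
lesion contrast per channel — and nothing else: no MRI physics, no
pathology realism. Preprocessing clips each channel at its 98th percentile
(linear-interpolation percentile over all voxels; the alternative over
non-zero voxels is a parameter) and z-scores using non-zero voxels only, so
background stays exactly zero. Scans are sliced along the last (axial)
axis, and splits are made at the unit level so slice leakage between splits
is impossible by construction, with floor allocation and the remainder to
train — 335 units at fractions 270/335, 30/335, 35/335 give exactly
(270, 30, 35).

The building scene places axis-aligned (optionally rotated) rectangles
with a minimum gap by seeded rejection sampling, including cul-de-sac
clusters of six closely spaced houses; the polygon set returned is the
exact vector truth of the rasterized mask. Dilating the mask by a couple of
pixels merges the clusters and reproduces the pixel-vs-instance metric
divergence on demand. What passing tests on these phantoms demonstrate is
that the geometric machinery is correct — not that any particular accuracy
would be reached on real scans or imagery, which would require trained
models and real data.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale:
phantoms of 40–64 pixels per side and a handful of slices, models of depth
0–2 with 2–4 base filters for forward passes (shape arithmetic is exercised
at full depth 4–5 symbolically), 20 seeds for the stochastic localization
property, and the full 64-pixel strip for the exhaustive impulse search.
These sizes were chosen so every property that is scale-free — which is all
of them; tile counts, shape recurrences, equivariance strides and metric
identities do not depend on image size — is tested in seconds. All
generators and models are pure functions of their seed, and experiment
reports embed the seed and a hash of their parameters so re-runs are
byte-comparable.

## Known limitations

* The engine runs single images, not batches, and has no training path;
  absolute outputs are not comparable to any trained network.
* Polygon IoU for pairs that are neither rectilinear nor convex falls back
  to supersampled rasterization (default 1/8-pixel grid) and is then
  approximate.
* The official building-footprint scorer may match instances slightly
  differently (its matcher and its treatment of IoU exactly 0.5 are not
  specified); results can differ marginally at the threshold.
* Sliding-window layouts clamp at the boundary; padding-based edge policies
  are deliberately not implemented.
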