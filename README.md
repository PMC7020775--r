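# tileseg

Tools for quantifying what tiled inference does to semantic segmentation.

Convolutional segmentation networks are routinely run on large medical and
satellite images by cropping tiles — four corners plus a center, or a
sliding window with 50% overlap — predicting each tile, and stitching the
results back together. Because pooling layers commit to a fixed grid, such
networks are shift-equivariant only at translations that are multiples of
their cumulative stride `2^depth`; tiling shifts the content relative to
that grid, so the stitched prediction is not the prediction on the whole
image, and the disagreements cluster along segmentation boundaries — the
part clinicians and mappers care about most. `tileseg` provides the
machinery to measure these effects reproducibly on synthetic data, for
method developers who want to audit a tiling pipeline rather than train a
model.

The package implements:

* **Tile geometry** — corner+center layouts (5 tiles in 2D, 9 in 3D),
  sliding windows with fractional overlap and boundary clamping, coverage
  maps, tile extraction/placement, JSON serialization.
* **Aggregation** — stitching per-tile probability maps by
  coverage-weighted averaging, under both *rounding after averaging*
  (average then threshold at 0.5) and *rounding before averaging*
  (threshold tiles, average the votes, threshold at 0.5), with half-up
  ties; slice stacking into volumes; PNG/NIfTI I/O.
* **Metrics** — pixelwise Dice `2·TP/(2·TP + FP + FN)` (empty/empty = 1),
  and instance-level polygon F1: connected-component polygonization with
  exact lattice boundaries and holes, geometric IoU, greedy one-to-one
  matching with a strict 0.5 cutoff, precision/recall/F1; GeoJSON I/O.
* **A from-scratch U-Net forward engine** — seeded deterministic weights,
  same-zero or valid padding, shape validation by walking the pooling flow
  (inputs must be divisible by `2^depth` when zero-padded; the valid-mode
  recurrence maps 236 → 52 at depth 4), max pooling, nearest-neighbour
  upsampling, instance norm, sigmoid head. No framework, no training.
* **Variance analysis** — flip and ±1/±2-pixel translation protocols with
  cross-Dice and gray/white/black trinary difference maps, equivariance
  classification per offset, and an exhaustive impulse search showing a
  3-layer 2×2 pool stack regains equivariance exactly at shifts of
  `2^3 = 8`.
* **Synthetic data** — seeded MRI-like phantoms (4-channel 240×240×155
  geometry, ellipsoidal tissue support, blob lesions), 98th-percentile
  clipping with non-zero z-scoring, axial slicing, leakage-free unit-level
  splits, and building scenes with exact vector ground truth including
  mergeable cul-de-sac clusters.

## A worked example

```r
library(tileseg)
set.seed(42)

# a blob on a noisy background
blob <- matrix(0, 64, 64)
for (r in 1:64) for (c in 1:64)
  if ((r - 32)^2 + (c - 30)^2 < 150) blob[r, c] <- 1.5
blob <- blob + matrix(rnorm(64 * 64, sd = 0.05), 64, 64)

model <- build_unet(unet_config(depth = 2, base_filters = 4,
                                in_channels = 1, seed = 3))
layout <- corner_center_layout(c(64, 64), c(32, 32))
layout
#> tile_layout (corner_center): 5 tile(s) over image (64x64)

whole  <- whole_image_inference(model, blob)
after  <- tiled_inference(model, blob, layout,
                          aggregation_config("round_after_averaging"))
before <- tiled_inference(model, blob, layout,
                          aggregation_config("round_before_averaging"))
sum(whole != after)    # tiled prediction is not the whole-image prediction
#> [1] 184
sum(after != before)   # and the two aggregation rules disagree with each other
#> [1] 56

# pixel metric vs instance metric: one blob over two buildings
gt <- matrix(0L, 20, 35); gt[6:15, 3:12] <- 1L; gt[6:15, 18:27] <- 1L
merged <- matrix(0L, 20, 35); merged[6:15, 3:27] <- 1L
dice(merged, gt)                                        # high
#> [1] 0.8888889
polygon_f1(polygonize(merged), polygonize(gt))$f1       # zero
#> [1] 0

# why: max pooling is translation-variant below its stride
equivariant_stride(pool_stack_shift_search(n_layers = 3))
#> [1] 8
```

A depth-2 model disagrees with itself at 184 of 4096 pixels purely because
of tiling, the two standard stitching rules disagree at another 56, a
merged two-building blob keeps Dice near 0.89 while matching zero polygons,
and the exhaustive impulse search certifies that three stacked 2×2 pools
are shift-equivariant exactly at multiples of 8 pixels.

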