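# Shared fixtures and independent brute-force oracles.

# image with pixel value row*W + col (0-based), handy for index arithmetic
ramp_image <- function(h, w) {
  outer(0:(h - 1), 0:(w - 1), function(r, c) r * w + c)
}

# brute-force coverage: per-pixel interval membership over all tiles
coverage_oracle <- function(layout) {
  counts <- array(0L, dim = layout$image_shape)
  grid <- expand.grid(lapply(layout$image_shape, seq_len))
  for (p in seq_len(nrow(grid))) {
    pos <- as.integer(grid[p, ]) - 1L  # 0-based
    n <- 0L
    for (t in layout$tiles) {
      if (all(pos >= t$offset & pos < t$offset + t$shape)) n <- n + 1L
    }
    counts[matrix(as.integer(grid[p, ]), 1)] <- n
  }
  counts
}

# brute-force stitching: accumulate and divide pixel by pixel
stitch_oracle <- function(tile_preds, layout) {
  acc <- array(0, dim = layout$image_shape)
  cnt <- array(0L, dim = layout$image_shape)
  grid <- expand.grid(lapply(layout$image_shape, seq_len))
  for (p in seq_len(nrow(grid))) {
    pos <- as.integer(grid[p, ])
    for (i in seq_along(layout$tiles)) {
      t <- layout$tiles[[i]]
      rel <- pos - t$offset
      if (all(rel >= 1L & rel <= t$shape)) {
        acc[matrix(pos, 1)] <- acc[matrix(pos, 1)] +
          tile_preds[[i]][matrix(rel, 1)]
        cnt[matrix(pos, 1)] <- cnt[matrix(pos, 1)] + 1L
      }
    }
  }
  out <- acc
  out[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  out[cnt == 0] <- 0
  out
}

# exhaustive optimal one-to-one matching (small instances only)
optimal_match_count <- function(proposals, ground_truth, iou_threshold = 0.5) {
  np <- length(proposals$polygons)
  ng <- length(ground_truth$polygons)
  iou <- matrix(0, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng))
    iou[i, j] <- polygon_iou(proposals$polygons[[i]],
                             ground_truth$polygons[[j]])
  best <- 0L
  recurse <- function(i, used_g, count) {
    if (i > np) {
      best <<- max(best, count)
      return(invisible())
    }
    recurse(i + 1L, used_g, count)  # leave proposal i unmatched
    for (j in seq_len(ng)) {
      if (!used_g[j] && iou[i, j] > iou_threshold) {
        used_g[j] <- TRUE
        recurse(i + 1L, used_g, count + 1L)
        used_g[j] <- FALSE
      }
    }
  }
  if (np > 0L && ng > 0L) recurse(1L, rep(FALSE, ng), 0L)
  best
}

# small MRI-like slice fixture: preprocessed 4-channel slice through the
# largest blob cross-section, plus its mask
blob_slice <- function(seed, shape = c(48, 48, 26), contrast = 3,
                       noise_sd = 0.05) {
  cfg <- scan_phantom_config(shape = shape, channels = 4, n_blobs = 1,
                             blob_radius = c(8, 12),
                             channel_offsets = rep(contrast, 4),
                             noise_sd = noise_sd, seed = seed)
  scan <- make_brats_like_scan(cfg)
  k <- which.max(apply(scan$mask, 3, sum))
  slice_scan(preprocess_scan(scan$volume), scan$mask)[[k]]
}

# pointwise intensity-threshold predictor: perfectly equivariant oracle
pointwise_predictor <- function(channel = 1, level = 1.5) {
  function(img) binarize(img[, , channel], level)
}
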