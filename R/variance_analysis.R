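# Flip and small-translation variance of segmentation functions.
#
# A "predict" function maps a channels-last image crop to an integer 0/1
# mask. Its output may be spatially smaller than the crop (valid-padding
# models); the prediction is then taken to sit at the center of the crop
# (symmetric margin, floor on odd differences), and all comparisons happen
# in image coordinates after translating predictions back to a common frame.

prediction_placement <- function(predict, image, spec) {
  crop <- extract_tile(image, spec)
  mask <- predict(crop)
  d <- length(spec$offset)
  out_shape <- as.integer(spatial_shape(mask, d))
  margin <- (spec$shape - out_shape) %/% 2L
  if (any(margin < 0L))
    stop("prediction larger than its input crop")
  list(mask = mask, offset = spec$offset + margin, shape = out_shape)
}

overlap_views <- function(pa, pb) {
  lo <- pmax(pa$offset, pb$offset)
  hi <- pmin(pa$offset + pa$shape, pb$offset + pb$shape)
  if (any(hi <= lo)) return(NULL)
  take <- function(p) {
    idx <- lapply(seq_along(lo), function(a)
      seq.int(lo[a] - p$offset[a] + 1L, hi[a] - p$offset[a]))
    do.call(`[`, c(list(p$mask), idx, list(drop = FALSE)))
  }
  list(a = take(pa), b = take(pb), offset = lo, shape = hi - lo)
}

#' Trinary difference map between two binary predictions
#'
#' Codes each pixel as `agree` (both predictions equal), `only_a`
#' (foreground in the first prediction only) or `only_b` (foreground in the
#' second only) — the gray/white/black encoding used to visualize where two
#' predictions of nominally the same content disagree.
#'
#' @param pred_a,pred_b Integer 0/1 arrays of identical shape.
#' @return List of class `trinary_diff` with `codes` (integer array: 0 =
#'   agree, 1 = only_a, 2 = only_b) and `counts` (named vector).
#' @export
trinary_diff <- function(pred_a, pred_b) {
  if (!identical(dim(pred_a), dim(pred_b)) ||
      length(pred_a) != length(pred_b))
    stop("predictions must have identical shapes")
  a <- as.integer(pred_a) != 0L
  b <- as.integer(pred_b) != 0L
  codes <- array(0L, dim = if (is.null(dim(pred_a))) length(pred_a)
                 else dim(pred_a))
  codes[a & !b] <- 1L
  codes[!a & b] <- 2L
  counts <- c(agree = sum(codes == 0L), only_a = sum(codes == 1L),
              only_b = sum(codes == 2L))
  structure(list(codes = codes, counts = counts), class = "trinary_diff")
}

#' @export
print.trinary_diff <- function(x, ...) {
  cat(sprintf("trinary_diff: %d agree, %d only_a, %d only_b\n",
              x$counts["agree"], x$counts["only_a"], x$counts["only_b"]))
  invisible(x)
}

# localization of disagreements around the ground-truth mask boundary:
# share of disagreeing pixels inside a band of `band` pixels around the
# boundary, and the per-pixel disagreement rates inside vs outside the band
# (the rates normalize for the band's small area)
boundary_band_stats <- function(codes, gt, band = 3) {
  na <- c(band_share = NA_real_, band_rate = NA_real_,
          outside_rate = NA_real_)
  gt <- matrix(as.integer(gt) != 0L, nrow(gt), ncol(gt))
  if (!any(gt) || all(gt)) return(na)
  grown <- dilate_mask(matrix(as.integer(gt), nrow(gt)), band) == 1L
  shrunk <- !(dilate_mask(matrix(as.integer(!gt), nrow(gt)), band) == 1L)
  band_px <- grown & !shrunk
  dis <- codes != 0L
  c(band_share = if (any(dis)) sum(dis & band_px) / sum(dis) else NA_real_,
    band_rate = sum(dis & band_px) / sum(band_px),
    outside_rate = sum(dis & !band_px) / sum(!band_px))
}

#' Flip variance of a segmentation function
#'
#' Predicts on the image and on its axis-flipped copy, un-flips the second
#' prediction so the two can be compared in the same frame, and reports the
#' Dice of each against the ground truth, the cross-Dice between the two
#' predictions, their trinary difference map, and how the disagreements
#' localize around the ground-truth boundary: the share of disagreeing
#' pixels falling within a 3-pixel band of the boundary, and the per-pixel
#' disagreement rate inside vs outside that band (flip-induced disagreement
#' tends to concentrate along segmentation borders, which shows up as a
#' higher in-band rate).
#'
#' @param predict Segmentation function (see module header).
#' @param image Channels-last 2D image array.
#' @param gt Integer 0/1 ground-truth mask with the image's spatial shape.
#' @param axis Spatial axis to flip: 1 (vertical, rows) or 2 (horizontal).
#' @return List of class `flip_report`: `axis`, `dice_normal`,
#'   `dice_flipped`, `cross_dice`, `diff`, and `boundary_band` (named
#'   vector: `band_share`, `band_rate`, `outside_rate`).
#' @export
flip_variance <- function(predict, image, gt, axis = 1) {
  d <- 2L
  if (!axis %in% c(1, 2)) stop("axis must be 1 or 2")
  sp <- spatial_shape(image, d)
  base <- tile_spec(rep(0L, d), sp)
  pn <- prediction_placement(predict, image, base)
  flipped <- flip_axis(image, axis)
  pf_raw <- predict(extract_tile(flipped, base))
  pf_mask <- flip_axis(pf_raw, axis)  # un-flip back into the normal frame
  pf <- list(mask = pf_mask, offset = pn$offset, shape = pn$shape)
  # ground truth restricted to the (possibly smaller) prediction region
  gt_region <- extract_tile(gt, tile_spec(pn$offset, pn$shape))
  dn <- dice(pn$mask, gt_region)
  df <- dice(pf$mask, gt_region)
  cd <- dice(pn$mask, pf$mask)
  diff <- trinary_diff(pn$mask, pf$mask)
  structure(list(axis = axis, dice_normal = dn, dice_flipped = df,
                 cross_dice = cd, diff = diff,
                 boundary_band = boundary_band_stats(diff$codes, gt_region)),
            class = "flip_report")
}

#' @export
print.flip_report <- function(x, ...) {
  cat(sprintf(
    "flip_report (axis %d): dice normal %.4f, flipped %.4f, cross %.4f\n",
    x$axis, x$dice_normal, x$dice_flipped, x$cross_dice))
  invisible(x)
}

offset_grid <- function(d, max_offset) {
  g <- expand.grid(rep(list(seq.int(-max_offset, max_offset)), d))
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

#' Translation variance of a segmentation function
#'
#' Takes a centered crop of the image, translates it by every non-zero
#' integer offset with components in `[-max_offset, max_offset]` (24 offsets
#' for the default 2-pixel radius in 2D), predicts on the center and on each
#' offset crop, and compares the two predictions on the region they share in
#' image coordinates. A perfectly shift-equivariant predictor scores
#' cross-Dice 1 at every offset.
#'
#' @param predict Segmentation function.
#' @param image Channels-last 2D image array.
#' @param crop_shape Integer spatial shape of the crop.
#' @param max_offset Maximum per-axis translation (default 2).
#' @return List of class `translation_report`: `base` (the center
#'   `tile_spec`) and `entries`, a named list (name `"di,dj"`) of lists with
#'   `offset`, `cross_dice`, `diff`, `overlap_shape`.
#' @export
translation_variance <- function(predict, image, crop_shape, max_offset = 2) {
  d <- length(crop_shape)
  sp <- spatial_shape(image, d)
  base <- tile_spec((sp - as.integer(crop_shape)) %/% 2L, crop_shape)
  check_tile_in_bounds(base, sp)
  p0 <- prediction_placement(predict, image, base)
  entries <- list()
  for (delta in offset_grid(d, max_offset)) {
    oc <- offset_crop(sp, base, delta)
    pd <- prediction_placement(predict, image, oc$spec)
    ov <- overlap_views(p0, pd)
    if (is.null(ov))
      stop("prediction windows do not overlap; crop too small for offset")
    diff <- trinary_diff(ov$a, ov$b)
    entries[[paste(delta, collapse = ",")]] <-
      list(offset = delta, cross_dice = dice(ov$a, ov$b), diff = diff,
           overlap_shape = ov$shape)
  }
  structure(list(base = base, entries = entries),
            class = "translation_report")
}

#' @export
print.translation_report <- function(x, ...) {
  cd <- vapply(x$entries, function(e) e$cross_dice, numeric(1))
  cat(sprintf(
    "translation_report: %d offsets, cross-dice min %.4f / mean %.4f\n",
    length(cd), min(cd), mean(cd)))
  invisible(x)
}

#' Shift-equivariance classification of a segmentation function
#'
#' For each requested offset, predicts on a centered crop and on the
#' translated crop and declares the offset `identical` when the two
#' predictions agree exactly on their full overlap (predictions are binary;
#' no tolerance). The verdict states whether every offset all of whose
#' components are multiples of `stride` came out identical — the expected
#' behaviour of a pooling stack with that cumulative stride.
#'
#' @param predict Segmentation function.
#' @param image Channels-last image.
#' @param crop_shape Crop spatial shape.
#' @param offsets List of integer offset vectors.
#' @param stride Claimed cumulative stride.
#' @return List with `results` (data.frame: offset label, stride multiple
#'   flag, identical flag) and `verdict` (logical).
#' @export
equivariance_check <- function(predict, image, crop_shape, offsets, stride) {
  d <- length(crop_shape)
  sp <- spatial_shape(image, d)
  base <- tile_spec((sp - as.integer(crop_shape)) %/% 2L, crop_shape)
  p0 <- prediction_placement(predict, image, base)
  rows <- lapply(offsets, function(delta) {
    delta <- as.integer(delta)
    if (length(delta) != d) stop("offset dimensionality mismatch")
    oc <- offset_crop(sp, base, delta)
    pd <- prediction_placement(predict, image, oc$spec)
    ov <- overlap_views(p0, pd)
    if (is.null(ov)) stop("no prediction overlap at offset")
    data.frame(offset = paste(delta, collapse = ","),
               stride_multiple = all(delta %% stride == 0L),
               identical = all(ov$a == ov$b))
  })
  results <- do.call(rbind, rows)
  verdict <- all(results$identical[results$stride_multiple])
  list(results = results, verdict = verdict)
}

# ---- worst-case impulse search over a pooling stack -----------------------

# image-coordinate prediction of an n-layer 2x pooling stack on a 1D window:
# pool the window n times, then paint each pooled value back over its 2^n
# input pixels (nearest-neighbour upsampling back to the window frame)
pool_stack_predict_1d <- function(x, n_layers) {
  p <- x
  for (i in seq_len(n_layers)) p <- maxpool(p, 2)
  rep(p, each = 2L^n_layers)
}

#' Exhaustive impulse search for pooling-stack shift variance
#'
#' On a 1D strip, slides a window of length `strip_len - max_shift` (a
#' multiple of the stack's cumulative stride) to every shift `s` in
#' `1..max_shift`, and searches over all single-impulse inputs for a
#' disagreement between the unshifted and shifted windows' pooled outputs on
#' their overlap, with outputs compared in strip coordinates. A stack of
#' `n_layers` 2x2 pools has cumulative stride `2^n_layers`: shifts that are
#' multiples of it can never disagree, every other shift admits an impulse
#' that does.
#'
#' @param n_layers Number of stacked 2x pooling layers (default 3).
#' @param strip_len Strip length (default 64).
#' @param max_shift Largest shift examined (default 16).
#' @return data.frame with `shift` and `differs` (whether any impulse
#'   produced a disagreement).
#' @export
pool_stack_shift_search <- function(n_layers = 3, strip_len = 64,
                                    max_shift = 16) {
  stride <- 2L^n_layers
  win <- strip_len - max_shift
  win <- (win %/% stride) * stride
  if (win < stride) stop("strip too short for the pooling stack")
  differs <- logical(max_shift)
  for (s in seq_len(max_shift)) {
    found <- FALSE
    for (q in seq_len(strip_len)) {
      x <- numeric(strip_len)
      x[q] <- 1
      p0 <- pool_stack_predict_1d(x[1:win], n_layers)
      ps <- pool_stack_predict_1d(x[(1 + s):(s + win)], n_layers)
      # overlap in strip coordinates: pixels s+1 .. win
      if (win > s &&
          any(p0[(s + 1):win] != ps[1:(win - s)])) {
        found <- TRUE
        break
      }
    }
    differs[s] <- found
  }
  data.frame(shift = seq_len(max_shift), differs = differs)
}

#' Stride at which a pooling stack regains shift equivariance
#'
#' Given a [pool_stack_shift_search()] table, returns the smallest shift
#' `s > 0` such that `s` and all its multiples within the table show no
#' disagreement while every non-multiple below the table's range admits one.
#'
#' @param search Output of [pool_stack_shift_search()].
#' @return The equivariant stride, or `NA` if no shift qualifies.
#' @export
equivariant_stride <- function(search) {
  max_shift <- max(search$shift)
  for (s in search$shift) {
    mult <- search$shift %% s == 0L
    if (!any(search$differs[mult]) && all(search$differs[!mult]))
      return(s)
  }
  NA_integer_
}

#' Write a trinary difference map as PNG
#'
#' Gray (128) = agree, white (255) = only in the first prediction,
#' black (0) = only in the second.
#'
#' @param diff A [trinary_diff()] with 2D codes.
#' @param path Output path.
#' @export
write_diff_png <- function(diff, path) {
  codes <- diff$codes
  img <- matrix(128 / 255, nrow(codes), ncol(codes))
  img[codes == 1L] <- 1
  img[codes == 2L] <- 0
  png::writePNG(img, path)
  invisible(path)
}
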