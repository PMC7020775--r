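# Stitching per-tile probability predictions into whole-image predictions.

#' Aggregation configuration
#'
#' The two rules for combining overlapping tile predictions:
#' `"round_after_averaging"` averages the tile probabilities pixelwise and
#' then thresholds once; `"round_before_averaging"` thresholds each tile
#' first, averages the resulting 0/1 votes, and thresholds the vote fraction
#' at 0.5. Thresholding is half-up: a value exactly at the threshold maps
#' to foreground.
#'
#' @param mode `"round_after_averaging"` or `"round_before_averaging"`.
#' @param threshold Probability threshold in (0, 1); default 0.5.
#' @return A list of class `aggregation_config`.
#' @export
aggregation_config <- function(mode = c("round_after_averaging",
                                        "round_before_averaging"),
                               threshold = 0.5) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(mode = mode, threshold = threshold, tie_rule = "half_up"),
            class = "aggregation_config")
}

#' Threshold a probability map half-up
#'
#' @param x Numeric array of probabilities.
#' @param threshold Threshold; values `>= threshold` become 1 (half-up ties).
#' @return Integer array of 0/1 with the same shape.
#' @export
binarize <- function(x, threshold = 0.5) {
  out <- array(as.integer(x >= threshold), dim = if (is.null(dim(x)))
    NULL else dim(x))
  out
}

check_tile_preds <- function(tile_preds, layout) {
  if (length(tile_preds) != length(layout$tiles))
    stop(sprintf("got %d predictions for %d tiles",
                 length(tile_preds), length(layout$tiles)))
  d <- length(layout$image_shape)
  for (i in seq_along(tile_preds)) {
    sp <- spatial_shape(tile_preds[[i]], d)
    if (!identical(as.integer(sp), layout$tiles[[i]]$shape))
      stop(sprintf("prediction %d has shape (%s) but tile has shape (%s)",
                   i, paste(sp, collapse = ","),
                   paste(layout$tiles[[i]]$shape, collapse = ",")))
  }
  invisible(TRUE)
}

#' Stitch tile probability maps by coverage-weighted averaging
#'
#' Each pixel of the output is the mean of the predictions of all tiles
#' covering it. Pixels covered by no tile are set to 0 and reported.
#'
#' @param tile_preds List of numeric arrays in `[0, 1]`, one per layout tile,
#'   each with the tile's spatial shape.
#' @param layout The `tile_layout` the predictions belong to.
#' @return A list of class `stitched_probability` with elements
#'   `probabilities` (numeric array, image shape), `coverage` (integer
#'   array), and `uncovered` (integer count of pixels with zero coverage).
#' @export
stitch_probabilities <- function(tile_preds, layout) {
  check_tile_preds(tile_preds, layout)
  acc <- array(0, dim = layout$image_shape)
  for (i in seq_along(tile_preds)) {
    t <- layout$tiles[[i]]
    idx <- lapply(seq_along(t$offset), function(a)
      seq.int(t$offset[a] + 1L, t$offset[a] + t$shape[a]))
    old <- do.call(`[`, c(list(acc), idx, list(drop = FALSE)))
    pred <- array(as.numeric(tile_preds[[i]]), dim = t$shape)
    acc <- do.call(`[<-`, c(list(acc), idx, list(value = old + pred)))
  }
  cov <- coverage_map(layout)
  prob <- acc
  covered <- cov > 0L
  prob[covered] <- acc[covered] / cov[covered]
  prob[!covered] <- 0
  structure(list(probabilities = prob, coverage = cov,
                 uncovered = sum(!covered)),
            class = "stitched_probability")
}

#' Aggregate tiles by averaging then rounding
#'
#' @inheritParams stitch_probabilities
#' @param config An [aggregation_config()]; its `threshold` is applied to the
#'   averaged probability map.
#' @return Integer 0/1 array with the layout's image shape; attribute
#'   `uncovered` carries the zero-coverage pixel count.
#' @export
aggregate_round_after <- function(tile_preds, layout,
                                  config = aggregation_config()) {
  st <- stitch_probabilities(tile_preds, layout)
  out <- binarize(st$probabilities, config$threshold)
  out[st$coverage == 0L] <- 0L
  attr(out, "uncovered") <- st$uncovered
  out
}

#' Aggregate tiles by rounding then averaging
#'
#' Each tile is thresholded to 0/1 first; the binary votes are averaged per
#' pixel over the covering tiles and the vote fraction is thresholded at 0.5
#' (half-up, so an exact tie votes foreground).
#'
#' @inheritParams aggregate_round_after
#' @return Integer 0/1 array as in [aggregate_round_after()].
#' @export
aggregate_round_before <- function(tile_preds, layout,
                                   config = aggregation_config()) {
  check_tile_preds(tile_preds, layout)
  rounded <- lapply(tile_preds, function(p)
    array(as.numeric(binarize(p, config$threshold)),
          dim = if (is.null(dim(p))) length(p) else dim(p)))
  st <- stitch_probabilities(rounded, layout)
  out <- binarize(st$probabilities, 0.5)
  out[st$coverage == 0L] <- 0L
  attr(out, "uncovered") <- st$uncovered
  out
}

#' Stack 2D slice masks into a 3D volume
#'
#' Inverse of slicing a volume along its last spatial axis: plane k of the
#' result equals slice k of the input list.
#'
#' @param slice_masks List of 2D arrays sharing one spatial shape.
#' @return 3D array of shape `(H, W, length(slice_masks))`.
#' @export
stack_slices <- function(slice_masks) {
  if (length(slice_masks) == 0L) stop("no slices to stack")
  ref <- dim(slice_masks[[1]])
  for (k in seq_along(slice_masks)) {
    if (!identical(dim(slice_masks[[k]]), ref))
      stop(sprintf("slice %d has shape (%s), expected (%s)", k,
                   paste(dim(slice_masks[[k]]), collapse = ","),
                   paste(ref, collapse = ",")))
  }
  out <- array(0L, dim = c(ref, length(slice_masks)))
  for (k in seq_along(slice_masks)) out[, , k] <- slice_masks[[k]]
  out
}

#' Write a 2D binary mask as PNG
#'
#' Foreground is written as 255, background as 0.
#' @param mask Integer 0/1 matrix.
#' @param path Output file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(array(as.numeric(mask), dim = dim(mask)), path)
  invisible(path)
}

#' Read a 2D binary mask from PNG
#'
#' Pixels above 0.5 (of the 0..1 PNG range) are foreground.
#' @param path PNG file path.
#' @return Integer 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  binarize(img, 0.5)
}

#' Write a 3D mask or volume as NIfTI
#'
#' An identity affine is used unless a reference image is supplied.
#' @param volume 3D (or 4D channels-last) numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param reference Optional `niftiImage` or path whose header to copy.
#' @export
write_volume_nifti <- function(volume, path, reference = NULL) {
  if (is.null(reference)) {
    RNifti::writeNifti(RNifti::asNifti(volume), path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(volume, reference = reference), path)
  }
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array (header dropped).
#' @export
read_volume_nifti <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}
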