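# End-to-end orchestration: tiled vs whole-image inference, tile-size
# sweeps, and variance report bundles.

as_forward_fn <- function(model) {
  if (inherits(model, "unet_model"))
    function(tile) unet_forward(model, tile)
  else if (is.function(model)) model
  else stop("model must be a unet_model or a function(tile) -> probability map")
}

#' Tiled inference over a layout
#'
#' Extracts every tile of the layout, runs the model on each, and aggregates
#' the per-tile probability maps into a whole-image binary mask under the
#' requested aggregation rule. The model's output must have the tile's
#' spatial shape (zero-padded models); with a single whole-image tile this
#' reduces to thresholded whole-image inference.
#'
#' @param model A [build_unet()] model or a `function(tile)` returning a
#'   probability map of the tile's shape.
#' @param image Channels-last image array.
#' @param layout A `tile_layout` over the image's spatial shape.
#' @param config An [aggregation_config()].
#' @return Integer 0/1 mask of the image's spatial shape, with attribute
#'   `uncovered` (count of pixels no tile covers).
#' @export
tiled_inference <- function(model, image, layout,
                            config = aggregation_config()) {
  fwd <- as_forward_fn(model)
  d <- length(layout$image_shape)
  sp <- spatial_shape(image, d)
  if (!identical(as.integer(sp), layout$image_shape))
    stop("layout image_shape does not match the image")
  preds <- lapply(layout$tiles, function(t) {
    p <- fwd(extract_tile(image, t))
    psp <- as.integer(spatial_shape(p, d))
    if (!identical(psp, t$shape))
      stop(sprintf(
        "model output shape (%s) incompatible with tile shape (%s); tiled stitching needs size-preserving models",
        paste(psp, collapse = ","), paste(t$shape, collapse = ",")))
    p
  })
  if (config$mode == "round_after_averaging")
    aggregate_round_after(preds, layout, config)
  else
    aggregate_round_before(preds, layout, config)
}

#' Whole-image inference
#'
#' @inheritParams tiled_inference
#' @param threshold Binarization threshold, default 0.5.
#' @return Integer 0/1 mask.
#' @export
whole_image_inference <- function(model, image, threshold = 0.5) {
  fwd <- as_forward_fn(model)
  binarize(fwd(image), threshold)
}

pooled_polygon_f1 <- function(counts) {
  tp <- sum(vapply(counts, function(x) x$tp, numeric(1)))
  np <- sum(vapply(counts, function(x) x$tp + x$fp, numeric(1)))
  ng <- sum(vapply(counts, function(x) x$tp + x$fn, numeric(1)))
  precision <- if (np == 0) 0 else tp / np
  recall <- if (ng == 0) 0 else tp / ng
  if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
}

#' Tile-size sweep
#'
#' For each tile size, runs sliding-window tiled inference (50% overlap by
#' default) on every evaluation image and reports the per-image-averaged
#' Dice and, when ground-truth polygons are supplied, the polygon F1 pooled
#' over the whole evaluation set (matched counts summed across images before
#' the harmonic mean — the instance metric is a set-level quantity). A
#' whole-image row is appended when requested.
#'
#' @param model As in [tiled_inference()].
#' @param dataset List of evaluation cases, each a list with `image`, `mask`
#'   and optionally `polygons` (a [polygon_set()]).
#' @param tile_sizes Integer vector of square tile sides.
#' @param include_whole Append a whole-image inference row (default TRUE).
#' @param overlap Sliding-window overlap fraction, default 0.5.
#' @param modes Aggregation modes to evaluate.
#' @param iou_threshold Polygon-match IoU cutoff, default 0.5.
#' @return data.frame of class `sweep_result`: `tile_size`, `mode`, `dice`,
#'   `polygon_f1` (NA without polygons).
#' @export
tile_size_sweep <- function(model, dataset, tile_sizes,
                            include_whole = TRUE, overlap = 0.5,
                            modes = c("round_after_averaging",
                                      "round_before_averaging"),
                            iou_threshold = 0.5) {
  rows <- list()
  eval_masks <- function(pred_fn, label, mode_label) {
    dices <- numeric(length(dataset))
    match_counts <- list()
    has_polys <- all(vapply(dataset, function(cs)
      !is.null(cs$polygons), logical(1)))
    for (i in seq_along(dataset)) {
      cs <- dataset[[i]]
      pred <- pred_fn(cs$image)
      dices[i] <- dice(pred, cs$mask)
      if (has_polys)
        match_counts[[i]] <- polygon_f1(polygonize(pred), cs$polygons,
                                        iou_threshold)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      tile_size = label, mode = mode_label, dice = mean(dices),
      polygon_f1 = if (has_polys) pooled_polygon_f1(match_counts)
      else NA_real_, stringsAsFactors = FALSE)
  }
  d <- length(spatial_shape(dataset[[1]]$mask,
                            length(dim(dataset[[1]]$mask))))
  for (ts in tile_sizes) {
    for (mode in modes) {
      cfg <- aggregation_config(mode)
      eval_masks(function(img) {
        sp <- spatial_shape(img, 2L)
        layout <- sliding_window_layout(sp, rep(as.integer(ts), 2L), overlap)
        tiled_inference(model, img, layout, cfg)
      }, as.character(ts), mode)
    }
  }
  if (include_whole)
    eval_masks(function(img) whole_image_inference(model, img), "whole",
               "whole")
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

experiment_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Flip/translation variance report over an evaluation set
#'
#' Runs [flip_variance()] (per axis) and [translation_variance()] for every
#' case and collects per-case cross-Dice summaries; optionally writes the
#' summary as JSON and the trinary difference maps as PNGs. The report
#' embeds the seed and a hash of the run parameters so re-runs are
#' byte-comparable.
#'
#' @param predict Segmentation function (e.g. [unet_predictor()]).
#' @param dataset List of cases with `image` and `mask`.
#' @param crop_shape Crop shape for the translation protocol.
#' @param max_offset Maximum translation offset, default 2.
#' @param axes Flip axes to evaluate, default `c(1, 2)`.
#' @param out_dir Optional directory for `variance_report.json` and diff
#'   PNGs.
#' @param seed Seed to record in the report metadata.
#' @return List of class `variance_report` with `meta` and `cases`.
#' @export
variance_report <- function(predict, dataset, crop_shape, max_offset = 2,
                            axes = c(1, 2), out_dir = NULL, seed = NA) {
  cases <- lapply(seq_along(dataset), function(i) {
    cs <- dataset[[i]]
    flips <- lapply(axes, function(ax)
      flip_variance(predict, cs$image, cs$mask, ax))
    names(flips) <- paste0("axis", axes)
    tr <- translation_variance(predict, cs$image, crop_shape, max_offset)
    list(
      flip = lapply(flips, function(fr)
        list(axis = fr$axis, dice_normal = fr$dice_normal,
             dice_flipped = fr$dice_flipped, cross_dice = fr$cross_dice,
             boundary_band = as.list(fr$boundary_band))),
      translation = lapply(tr$entries, function(e)
        list(offset = e$offset, cross_dice = e$cross_dice,
             overlap_shape = e$overlap_shape)),
      diffs = list(flip = lapply(flips, function(fr) fr$diff),
                   translation = lapply(tr$entries, function(e) e$diff)))
  })
  meta <- list(seed = seed, crop_shape = as.integer(crop_shape),
               max_offset = max_offset, axes = axes,
               n_cases = length(dataset))
  meta$hash <- experiment_hash(meta)
  rep <- structure(list(meta = meta,
                        cases = lapply(cases, function(cs)
                          cs[c("flip", "translation")])),
                   class = "variance_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(rep),
                         file.path(out_dir, "variance_report.json"),
                         auto_unbox = TRUE, digits = NA)
    for (i in seq_along(cases)) {
      for (nm in names(cases[[i]]$diffs$flip))
        write_diff_png(cases[[i]]$diffs$flip[[nm]],
                       file.path(out_dir,
                                 sprintf("case%02d_flip_%s.png", i, nm)))
    }
  }
  rep
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf("variance_report: %d case(s), crop (%s), max offset %d\n",
              x$meta$n_cases, paste(x$meta$crop_shape, collapse = "x"),
              x$meta$max_offset))
  invisible(x)
}
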