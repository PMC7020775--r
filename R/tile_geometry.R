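# Tile layout generation and manipulation.
#
# Conventions used throughout the package: spatial coordinates are 0-based
# with half-open extents [offset, offset + shape); arrays are channels-last,
# i.e. (H, W) or (H, W, C) in 2D and (H, W, D) or (H, W, D, C) in 3D.

#' Create a tile specification
#'
#' A tile is an axis-aligned window into an image, described by a 0-based
#' offset and a shape, one entry per spatial axis. The extent on axis i is
#' the half-open interval `[offset[i], offset[i] + shape[i])`.
#'
#' @param offset Integer vector of 0-based offsets, one per spatial axis.
#' @param shape Integer vector of tile side lengths (pixels), same length as
#'   `offset`; every entry must be >= 1.
#' @return An object of class `tile_spec`.
#' @export
tile_spec <- function(offset, shape) {
  offset <- as.integer(offset)
  shape <- as.integer(shape)
  if (length(offset) != length(shape))
    stop("offset and shape must have the same length")
  if (any(offset < 0L)) stop("tile offsets must be non-negative")
  if (any(shape < 1L)) stop("tile shape entries must be >= 1")
  structure(list(offset = offset, shape = shape), class = "tile_spec")
}

#' @export
print.tile_spec <- function(x, ...) {
  cat(sprintf("tile_spec: offset (%s), shape (%s)\n",
              paste(x$offset, collapse = ","),
              paste(x$shape, collapse = ",")))
  invisible(x)
}

check_tile_in_bounds <- function(spec, image_shape, what = "tile") {
  image_shape <- as.integer(image_shape)
  if (length(spec$offset) != length(image_shape))
    stop(sprintf("%s dimensionality (%d) does not match image (%d)",
                 what, length(spec$offset), length(image_shape)))
  bad <- which(spec$offset + spec$shape > image_shape)
  if (length(bad) > 0L)
    stop(sprintf("%s exceeds image bounds on axis %d (offset %d + shape %d > %d)",
                 what, bad[1], spec$offset[bad[1]], spec$shape[bad[1]],
                 image_shape[bad[1]]))
  invisible(TRUE)
}

new_tile_layout <- function(image_shape, tiles, scheme) {
  image_shape <- as.integer(image_shape)
  for (t in tiles) check_tile_in_bounds(t, image_shape)
  # drop exact duplicate placements, keep first occurrence
  keys <- vapply(tiles, function(t)
    paste(c(t$offset, t$shape), collapse = ","), character(1))
  tiles <- tiles[!duplicated(keys)]
  structure(list(image_shape = image_shape, tiles = tiles, scheme = scheme),
            class = "tile_layout")
}

#' @export
print.tile_layout <- function(x, ...) {
  cat(sprintf("tile_layout (%s): %d tile(s) over image (%s)\n",
              x$scheme, length(x$tiles),
              paste(x$image_shape, collapse = "x")))
  invisible(x)
}

#' @export
length.tile_layout <- function(x) length(x$tiles)

#' Corner-plus-center tile layout
#'
#' Places one tile at each corner of the image (2^d corners for a
#' d-dimensional image) plus one centered tile, the layout used for fixed
#' five-tile (2D) and nine-tile (3D) inference. Corner offsets per axis are 0
#' or `image - tile`; the center offset is `floor((image - tile) / 2)`.
#' Coincident placements (arising when tile size equals image size on every
#' axis, or when the center falls on a corner) are deduplicated, so the tile
#' count is 2^d + 1 only when all placements are distinct. Corners come in
#' lexicographic offset order, the center tile last.
#'
#' @param image_shape Integer vector of spatial image dimensions (2 or 3).
#' @param tile_shape Integer vector of tile dimensions, same length.
#' @return A `tile_layout` with scheme `"corner_center"`.
#' @examples
#' corner_center_layout(c(240, 240), c(128, 128))        # 5 tiles
#' corner_center_layout(c(240, 240, 155), c(128, 128, 128)) # 9 tiles
#' @export
corner_center_layout <- function(image_shape, tile_shape) {
  image_shape <- as.integer(image_shape)
  tile_shape <- as.integer(tile_shape)
  d <- length(image_shape)
  if (!d %in% c(2L, 3L)) stop("image must be 2- or 3-dimensional")
  if (length(tile_shape) != d)
    stop("tile_shape must match image dimensionality")
  bad <- which(tile_shape > image_shape)
  if (length(bad) > 0L)
    stop(sprintf("tile larger than image on axis %d (%d > %d)",
                 bad[1], tile_shape[bad[1]], image_shape[bad[1]]))
  margin <- image_shape - tile_shape
  # corners: per-axis offset 0 or margin, lexicographic order
  choices <- lapply(margin, function(m) unique(c(0L, m)))
  grid <- expand.grid(rev(choices), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  tiles <- lapply(seq_len(nrow(grid)), function(i)
    tile_spec(as.integer(grid[i, ]), tile_shape))
  tiles <- c(tiles, list(tile_spec(margin %/% 2L, tile_shape)))
  new_tile_layout(image_shape, tiles, "corner_center")
}

#' Sliding-window tile layout
#'
#' Regular grid of tiles with a fixed fractional overlap between neighbours
#' on every axis (0.5 gives the common half-tile overlap). Per axis the
#' offsets are 0, s, 2s, ... with stride `s = round(tile * (1 - overlap))`;
#' the final offset is clamped to `image - tile` so the image boundary is
#' always covered. The layout is the Cartesian product of per-axis offsets
#' and its union covers every pixel.
#'
#' @param image_shape,tile_shape Integer vectors as in
#'   [corner_center_layout()].
#' @param overlap_fraction Fractional overlap between adjacent tiles, in
#'   `[0, 1)`. Default 0.5.
#' @return A `tile_layout` with scheme `"sliding_window"`.
#' @examples
#' sliding_window_layout(c(256, 256), c(128, 128), 0.5)  # 9 tiles
#' @export
sliding_window_layout <- function(image_shape, tile_shape,
                                  overlap_fraction = 0.5) {
  image_shape <- as.integer(image_shape)
  tile_shape <- as.integer(tile_shape)
  d <- length(image_shape)
  if (length(tile_shape) != d)
    stop("tile_shape must match image dimensionality")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  bad <- which(tile_shape > image_shape)
  if (length(bad) > 0L)
    stop(sprintf("tile larger than image on axis %d (%d > %d)",
                 bad[1], tile_shape[bad[1]], image_shape[bad[1]]))
  stride <- as.integer(round(tile_shape * (1 - overlap_fraction)))
  if (any(stride < 1L))
    stop("overlap_fraction yields a zero stride; tiles would not advance")
  axis_offsets <- lapply(seq_len(d), function(i) {
    last <- image_shape[i] - tile_shape[i]
    off <- seq.int(0L, max(last, 0L), by = stride[i])
    if (off[length(off)] < last) off <- c(off, last)
    off[off > last] <- last
    unique(as.integer(off))
  })
  grid <- expand.grid(rev(axis_offsets), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  tiles <- lapply(seq_len(nrow(grid)), function(i)
    tile_spec(as.integer(grid[i, ]), tile_shape))
  new_tile_layout(image_shape, tiles, if (length(tiles) == 1L) "single"
                  else "sliding_window")
}

#' Single whole-image layout
#'
#' Convenience layout with one tile covering the entire image.
#' @param image_shape Integer vector of spatial dimensions.
#' @return A `tile_layout` with scheme `"single"`.
#' @export
single_layout <- function(image_shape) {
  image_shape <- as.integer(image_shape)
  new_tile_layout(image_shape,
                  list(tile_spec(rep(0L, length(image_shape)), image_shape)),
                  "single")
}

spatial_shape <- function(image, ndim) {
  dm <- dim(image)
  if (is.null(dm)) dm <- length(image)
  if (length(dm) == ndim) dm else dm[seq_len(ndim)]
}

#' Extract a tile from an image
#'
#' Pure read of the window described by `spec`. The image may carry a
#' trailing channel axis (channels-last); channels are preserved.
#'
#' @param image Array whose leading dimensions are spatial.
#' @param spec A [tile_spec()] with as many axes as the image has spatial
#'   dimensions.
#' @return Array with spatial shape `spec$shape`, channels preserved.
#' @export
extract_tile <- function(image, spec) {
  d <- length(spec$offset)
  sp <- spatial_shape(image, d)
  check_tile_in_bounds(spec, sp)
  idx <- lapply(seq_len(d), function(i)
    seq.int(spec$offset[i] + 1L, spec$offset[i] + spec$shape[i]))
  dm <- dim(image)
  if (is.null(dm)) dm <- length(image)
  if (length(dm) > d) idx <- c(idx, lapply(dm[-seq_len(d)], seq_len))
  out <- do.call(`[`, c(list(image), idx, list(drop = FALSE)))
  if (length(dm) == d && d == 1L) out <- as.vector(out)
  out
}

#' Place a tile's values back into an image-sized array
#'
#' Inverse of [extract_tile()]; used by stitching and in round-trip checks.
#' @param canvas Array with image spatial shape (channels optional).
#' @param tile Array with `spec$shape` spatial shape.
#' @param spec The placement.
#' @return `canvas` with the window overwritten.
#' @export
place_tile <- function(canvas, tile, spec) {
  d <- length(spec$offset)
  sp <- spatial_shape(canvas, d)
  check_tile_in_bounds(spec, sp)
  idx <- lapply(seq_len(d), function(i)
    seq.int(spec$offset[i] + 1L, spec$offset[i] + spec$shape[i]))
  dm <- dim(canvas)
  if (is.null(dm)) dm <- length(canvas)
  if (length(dm) > d) idx <- c(idx, lapply(dm[-seq_len(d)], seq_len))
  do.call(`[<-`, c(list(canvas), idx, list(value = tile)))
}

#' Per-pixel tile coverage counts
#'
#' Counts, for every pixel, how many tiles of the layout contain it. The
#' total over the grid equals the summed tile areas/volumes; the minimum is
#' >= 1 exactly when the layout covers the image.
#'
#' @param layout A `tile_layout`.
#' @return Integer array of shape `layout$image_shape`.
#' @export
coverage_map <- function(layout) {
  counts <- array(0L, dim = layout$image_shape)
  for (t in layout$tiles) {
    idx <- lapply(seq_along(t$offset), function(i)
      seq.int(t$offset[i] + 1L, t$offset[i] + t$shape[i]))
    old <- do.call(`[`, c(list(counts), idx, list(drop = FALSE)))
    counts <- do.call(`[<-`, c(list(counts), idx, list(value = old + 1L)))
  }
  counts
}

#' Translate a tile and report the overlap with its base placement
#'
#' Used by the translation-variance protocol: the crop is shifted by a small
#' integer offset and predictions are later compared on the region the two
#' placements share. No clamping is applied — a translation that leaves the
#' image is an error, because variance analysis requires exact offsets.
#'
#' @param image Array the tiles index into (only its spatial shape is used),
#'   or an integer vector giving the spatial shape directly.
#' @param base A [tile_spec()].
#' @param delta Integer translation, one entry per axis.
#' @return A list with `spec` (the translated `tile_spec`), and the overlap
#'   between base and translated tile: `overlap_shape`, `overlap_image`
#'   (0-based offset of the overlap in image coordinates), `overlap_in_base`
#'   and `overlap_in_translated` (0-based offsets tile-locally).
#' @export
offset_crop <- function(image, base, delta) {
  d <- length(base$offset)
  sp <- if (is.numeric(image) && is.null(dim(image)) && length(image) == d &&
            all(image == round(image)) && d > 1L) as.integer(image)
        else spatial_shape(image, d)
  delta <- as.integer(delta)
  if (length(delta) != d) stop("delta must match tile dimensionality")
  new_off <- base$offset + delta
  if (any(new_off < 0L))
    stop("translated tile leaves the image (negative offset)")
  moved <- tile_spec(new_off, base$shape)
  check_tile_in_bounds(moved, sp, what = "translated tile")
  lo <- pmax(base$offset, moved$offset)
  hi <- pmin(base$offset + base$shape, moved$offset + moved$shape)
  if (any(hi <= lo)) {
    overlap_shape <- rep(0L, d)
    lo <- rep(NA_integer_, d)
  } else overlap_shape <- hi - lo
  list(spec = moved,
       overlap_shape = as.integer(overlap_shape),
       overlap_image = lo,
       overlap_in_base = lo - base$offset,
       overlap_in_translated = lo - moved$offset)
}

#' Serialize a tile layout to JSON
#'
#' @param layout A `tile_layout`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
layout_to_json <- function(layout, path = NULL) {
  obj <- list(image_shape = layout$image_shape,
              scheme = layout$scheme,
              tiles = lapply(layout$tiles, function(t)
                list(offset = t$offset, shape = t$shape)))
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a tile layout from JSON
#'
#' @param x A file path or JSON string produced by [layout_to_json()].
#' @return A `tile_layout`.
#' @export
layout_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyDataFrame = FALSE)
  tiles <- lapply(obj$tiles, function(t) tile_spec(t$offset, t$shape))
  new_tile_layout(obj$image_shape, tiles, obj$scheme)
}
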