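# Seeded generators standing in for multi-parametric MRI scans and
# building-footprint scenes, plus the preprocessing, slicing, augmentation
# and leakage-free splitting applied to them.

#' Configuration for an MRI-like scan phantom
#'
#' The phantom emulates the geometry of a multi-parametric brain MRI: a
#' 4-channel 240 x 240 x 155 volume that is exactly zero outside an
#' ellipsoidal tissue support, with one or more blob-like foreground lesions
#' whose union defines the ground-truth mask. Each channel gets a distinct
#' lesion contrast so the channels are non-redundant; no claim of MRI
#' physics realism is made.
#'
#' @param shape Spatial dims, default `c(240, 240, 155)`.
#' @param channels Number of channels, default 4.
#' @param n_blobs Number of lesion blobs, default 3.
#' @param blob_radius Radius range in voxels, default `c(8, 25)`.
#' @param channel_offsets Per-channel lesion contrast added inside blobs;
#'   recycled to `channels`. Default `c(1.2, 1.8, 0.8, 1.5)`.
#' @param tissue_level Mean intensity of non-lesion tissue, default 1.
#' @param support_fraction Semi-axes of the tissue ellipsoid as a fraction
#'   of the half-shape, default 0.9.
#' @param noise_sd Gaussian noise SD inside the support, default 0.1.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `scan_phantom_config`.
#' @export
scan_phantom_config <- function(shape = c(240, 240, 155), channels = 4,
                                n_blobs = 3, blob_radius = c(8, 25),
                                channel_offsets = c(1.2, 1.8, 0.8, 1.5),
                                tissue_level = 1, support_fraction = 0.9,
                                noise_sd = 0.1, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive dims")
  if (channels < 1) stop("channels must be >= 1")
  if (max(blob_radius) * 2 > min(shape))
    stop("blob radius exceeds the volume")
  structure(list(shape = shape, channels = as.integer(channels),
                 n_blobs = as.integer(n_blobs),
                 blob_radius = blob_radius,
                 channel_offsets = rep_len(channel_offsets, channels),
                 tissue_level = tissue_level,
                 support_fraction = support_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scan_phantom_config")
}

#' Generate an MRI-like scan phantom
#'
#' @param config A [scan_phantom_config()].
#' @return List with `volume` (`(H, W, D, channels)` array, zero outside the
#'   tissue support) and `mask` (`(H, W, D)` integer 0/1 lesion mask, the
#'   union of the blobs). Bit-identical across runs for a given config.
#' @export
make_brats_like_scan <- function(config) {
  stopifnot(inherits(config, "scan_phantom_config"))
  sh <- config$shape
  ctr <- (sh + 1) / 2
  semi <- config$support_fraction * sh / 2
  gx <- (seq_len(sh[1]) - ctr[1]) / semi[1]
  gy <- (seq_len(sh[2]) - ctr[2]) / semi[2]
  gz <- (seq_len(sh[3]) - ctr[3]) / semi[3]
  e2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  support <- e2 <= 1
  with_seed(config$seed, {
    mask <- array(FALSE, dim = sh)
    if (config$n_blobs > 0L) {
      for (b in seq_len(config$n_blobs)) {
        r <- stats::runif(1, config$blob_radius[1], config$blob_radius[2])
        # center well inside the support so the lesion stays in tissue
        u <- stats::runif(3, -0.5, 0.5)
        cx <- ctr + u * semi
        d2 <- outer(outer((seq_len(sh[1]) - cx[1])^2,
                          (seq_len(sh[2]) - cx[2])^2, `+`),
                    (seq_len(sh[3]) - cx[3])^2, `+`)
        mask <- mask | (d2 <= r^2)
      }
    }
    mask <- mask & support
    vol <- array(0, dim = c(sh, config$channels))
    for (ch in seq_len(config$channels)) {
      v <- array(0, dim = sh)
      n_in <- sum(support)
      v[support] <- config$tissue_level +
        stats::rnorm(n_in, sd = config$noise_sd)
      v[mask] <- v[mask] + config$channel_offsets[ch]
      v[support] <- pmax(v[support], 1e-3)  # keep tissue strictly non-zero
      vol[, , , ch] <- v
    }
    list(volume = vol, mask = array(as.integer(mask), dim = sh))
  })
}

#' Clip and z-score a multi-channel volume
#'
#' Per channel: values are clipped at the channel's 98th percentile
#' (linear-interpolation percentile over all voxels), then standardized
#' using the mean and standard deviation of the non-zero voxels only, so the
#' zero background stays exactly zero and is consistent across images. A
#' channel with no non-zero voxels is left untouched with a warning.
#'
#' @param volume Channels-last array (last axis = channels).
#' @param clip_percentile Clipping percentile in (0, 1], default 0.98.
#' @return Normalized array of the same shape.
#' @export
preprocess_scan <- function(volume, clip_percentile = 0.98) {
  dm <- dim(volume)
  nch <- dm[length(dm)]
  flat <- matrix(volume, ncol = nch)
  for (ch in seq_len(nch)) {
    v <- flat[, ch]
    nz <- v != 0
    if (!any(nz)) {
      warning(sprintf("channel %d has no non-zero voxels; left untouched", ch))
      next
    }
    q <- stats::quantile(v, clip_percentile, names = FALSE, type = 7)
    v <- pmin(v, q)
    nz <- v != 0
    m <- mean(v[nz])
    s <- stats::sd(v[nz])
    if (s > 0) v[nz] <- (v[nz] - m) / s else v[nz] <- 0
    flat[, ch] <- v
  }
  array(flat, dm)
}

#' Slice a volume and mask into 2D pairs
#'
#' One pair per plane along the last spatial (axial) axis; re-stacking the
#' mask slices with [stack_slices()] reproduces the volume mask.
#'
#' @param volume `(H, W, D, C)` array.
#' @param mask `(H, W, D)` integer mask.
#' @return List of `list(image = (H, W, C), mask = (H, W))`, length `D`.
#' @export
slice_scan <- function(volume, mask) {
  dv <- dim(volume); dmk <- dim(mask)
  if (length(dv) != 4L || length(dmk) != 3L ||
      !identical(dv[1:3], dmk))
    stop("volume must be (H,W,D,C) and mask (H,W,D) with matching dims")
  lapply(seq_len(dv[3]), function(k)
    list(image = array(volume[, , k, ], c(dv[1], dv[2], dv[4])),
         mask = matrix(mask[, , k], dv[1], dv[2])))
}

#' Leakage-free unit-level split
#'
#' Randomly partitions units (patients, scenes) into train/validation/test,
#' so that everything derived from one unit (e.g. all 2D slices of a scan)
#' lands in exactly one split. Sizes are the floor allocation of the
#' fractions with the remainder assigned to train.
#'
#' @param unit_ids Vector of unique unit identifiers.
#' @param fractions Length-3 numeric `(train, validation, test)` summing
#'   to 1.
#' @param seed Integer seed.
#' @return List of class `split_assignment` with `assignment` (data.frame:
#'   `unit`, `split`), `counts` and `fractions`.
#' @export
split_by_unit <- function(unit_ids, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  if (anyDuplicated(unit_ids)) stop("unit_ids must be unique")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(unit_ids)
  n_val <- as.integer(floor(n * fractions[2]))
  n_test <- as.integer(floor(n * fractions[3]))
  n_train <- n - n_val - n_test
  if (n < sum(c(n_train, n_val, n_test) > 0))
    stop("fewer units than non-empty splits")
  perm <- with_seed(seed, sample.int(n))
  split <- rep("train", n)
  split[perm[seq_len(n_val) + n_train]] <- "validation"
  if (n_test > 0)
    split[perm[seq_len(n_test) + n_train + n_val]] <- "test"
  split[perm[seq_len(n_train)]] <- "train"
  assignment <- data.frame(unit = unit_ids, split = split,
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment,
                 counts = c(train = n_train, validation = n_val,
                            test = n_test),
                 fractions = fractions),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment: %d train, %d validation, %d test\n",
              x$counts["train"], x$counts["validation"], x$counts["test"]))
  invisible(x)
}

#' Configuration for a synthetic building scene
#'
#' Rectangular "buildings" on a darker background, including cul-de-sac
#' clusters of closely spaced houses whose small gaps make them easy for a
#' coarse segmenter to merge — the situation where pixelwise Dice stays high
#' while the instance-level polygon F1 collapses.
#'
#' @param image_size `c(H, W)`, default `c(650, 650)`.
#' @param n_buildings Stand-alone buildings, default 14.
#' @param size_range Rectangle side range in pixels, default `c(25, 60)`.
#' @param min_gap Minimum gap between buildings in pixels, default 5.
#' @param culdesac_size Houses per cul-de-sac cluster, default 6.
#' @param n_culdesacs Number of clusters, default 2.
#' @param culdesac_gap Gap between cluster houses, default 3.
#' @param rotation_range Building rotation range in degrees, default
#'   `c(0, 0)` (axis-aligned, which keeps polygonization round-trips exact).
#' @param seed Integer seed.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(image_size = c(650, 650), n_buildings = 14,
                         size_range = c(25, 60), min_gap = 5,
                         culdesac_size = 6, n_culdesacs = 2,
                         culdesac_gap = 3, rotation_range = c(0, 0),
                         seed = 1L) {
  image_size <- as.integer(image_size)
  if (min_gap < 0) stop("min_gap must be >= 0")
  structure(list(image_size = image_size,
                 n_buildings = as.integer(n_buildings),
                 size_range = size_range, min_gap = min_gap,
                 culdesac_size = as.integer(culdesac_size),
                 n_culdesacs = as.integer(n_culdesacs),
                 culdesac_gap = culdesac_gap,
                 rotation_range = rotation_range,
                 seed = as.integer(seed)),
            class = "scene_config")
}

rect_ring <- function(r0, c0, hh, ww) {
  # pixel rows r0..r0+hh-1, cols c0..c0+ww-1 (1-based) -> lattice ring
  cbind(c(c0 - 1, c0 - 1 + ww, c0 - 1 + ww, c0 - 1),
        c(r0 - 1, r0 - 1, r0 - 1 + hh, r0 - 1 + hh))
}

rotate_ring <- function(ring, degrees) {
  th <- degrees * pi / 180
  ctr <- colMeans(ring)
  rel <- sweep(ring, 2, ctr)
  rot <- cbind(rel[, 1] * cos(th) - rel[, 2] * sin(th),
               rel[, 1] * sin(th) + rel[, 2] * cos(th))
  sweep(rot, 2, ctr, `+`)
}

#' Generate a synthetic building scene
#'
#' Buildings are placed by seeded rejection sampling honouring the minimum
#' gap; each cul-de-sac cluster is a 2 x 3 block of houses separated by
#' `culdesac_gap`. The returned polygons are the exact vector ground truth
#' of the rasterized mask.
#'
#' @param config A [scene_config()].
#' @return List with `image` (`(H, W, 3)` RGB array in `[0, 1]`), `mask`
#'   (integer 0/1 matrix) and `polygons` (a [polygon_set()]).
#' @export
make_building_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  gap <- config$min_gap
  with_seed(config$seed, {
    boxes <- matrix(numeric(0), 0, 4)  # r0, c0, r1, c1 bounding boxes
    rings <- list()
    fits <- function(box) {
      if (box[1] < 1 || box[2] < 1 || box[3] > h || box[4] > w) return(FALSE)
      if (nrow(boxes) == 0L) return(TRUE)
      !any(box[1] - gap <= boxes[, 3] & box[3] + gap >= boxes[, 1] &
             box[2] - gap <= boxes[, 4] & box[4] + gap >= boxes[, 2])
    }
    draw_angle <- function() {
      if (diff(range(config$rotation_range)) == 0)
        config$rotation_range[1]
      else stats::runif(1, config$rotation_range[1], config$rotation_range[2])
    }
    add_rect <- function(r0, c0, hh, ww, angle) {
      ring <- rect_ring(r0, c0, hh, ww)
      if (angle != 0) ring <- rotate_ring(ring, angle)
      rings[[length(rings) + 1L]] <<- ring
      bb <- c(min(ring[, 2]) + 1, min(ring[, 1]) + 1,
              max(ring[, 2]), max(ring[, 1]))
      boxes <<- rbind(boxes, bb)
    }
    # cul-de-sac clusters: 2 x 3 grids of small houses
    house <- round(mean(config$size_range) * 0.5)
    cg <- config$culdesac_gap
    n_rows <- 2L
    n_cols <- ceiling(config$culdesac_size / n_rows)
    clus_h <- n_rows * house + (n_rows - 1) * cg
    clus_w <- n_cols * house + (n_cols - 1) * cg
    for (k in seq_len(config$n_culdesacs)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        r0 <- floor(stats::runif(1, 1, max(h - clus_h, 1) + 1))
        c0 <- floor(stats::runif(1, 1, max(w - clus_w, 1) + 1))
        if (fits(c(r0, c0, r0 + clus_h - 1, c0 + clus_w - 1))) {
          placed <- TRUE
          cnt <- 0L
          for (i in seq_len(n_rows)) for (j in seq_len(n_cols)) {
            if (cnt >= config$culdesac_size) break
            add_rect(r0 + (i - 1) * (house + cg),
                     c0 + (j - 1) * (house + cg), house, house, 0)
            cnt <- cnt + 1L
          }
          break
        }
      }
      if (!placed) stop("could not place cul-de-sac cluster; packing infeasible")
    }
    for (k in seq_len(config$n_buildings)) {
      placed <- FALSE
      for (try in seq_len(500)) {
        hh <- round(stats::runif(1, config$size_range[1], config$size_range[2]))
        ww <- round(stats::runif(1, config$size_range[1], config$size_range[2]))
        r0 <- floor(stats::runif(1, 1, max(h - hh, 1) + 1))
        c0 <- floor(stats::runif(1, 1, max(w - ww, 1) + 1))
        ang <- draw_angle()
        pad <- if (ang != 0) ceiling((sqrt(2) - 1) * max(hh, ww) / 2) else 0
        if (fits(c(r0 - pad, c0 - pad, r0 + hh - 1 + pad, c0 + ww - 1 + pad))) {
          add_rect(r0, c0, hh, ww, ang)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place building; packing infeasible")
    }
    polys <- polygon_set(lapply(rings, mask_polygon))
    mask <- rasterize_polygons(polys, c(h, w))
    img <- array(0, dim = c(h, w, 3))
    base <- c(0.25, 0.22, 0.2)
    roof <- c(0.85, 0.8, 0.75)
    for (ch in 1:3) {
      plane <- matrix(base[ch], h, w) +
        matrix(stats::rnorm(h * w, sd = 0.02), h, w)
      plane[mask == 1L] <- roof[ch] + stats::rnorm(sum(mask), sd = 0.02)
      img[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    list(image = img, mask = mask, polygons = polys)
  })
}

# ---- augmentation ---------------------------------------------------------

rotate_plane <- function(x, degrees, interp) {
  h <- nrow(x); w <- ncol(x)
  th <- degrees * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  grid <- expand.grid(r = seq_len(h), c = seq_len(w))
  dr <- grid$r - cr; dc <- grid$c - cc
  # backward map: rotate output coordinates by -theta to find the source
  sr <- cr + dr * cos(th) - dc * sin(th)
  sc <- cc + dr * sin(th) + dc * cos(th)
  out <- matrix(0, h, w)
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out[cbind(grid$r[ok], grid$c[ok])] <- x[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    ok <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
    v <- (1 - fr[ok]) * (1 - fc[ok]) * x[cbind(r0[ok], c0[ok])] +
      (1 - fr[ok]) * fc[ok] * x[cbind(r0[ok], c0[ok] + 1)] +
      fr[ok] * (1 - fc[ok]) * x[cbind(r0[ok] + 1, c0[ok])] +
      fr[ok] * fc[ok] * x[cbind(r0[ok] + 1, c0[ok] + 1)]
    out[cbind(grid$r[ok], grid$c[ok])] <- v
  }
  out
}

#' Apply a fixed geometric augmentation to an image/mask pair
#'
#' The identical transform is applied to image and mask; flips and 90-degree
#' rotations permute pixels exactly, arbitrary-angle rotation resamples with
#' bilinear interpolation for the image and nearest-neighbour for the mask
#' (so the mask stays binary), filling exposed corners with 0.
#'
#' @param image `(H, W, C)` array or matrix.
#' @param mask Integer 0/1 matrix.
#' @param flip_v,flip_h Flip vertically (rows) / horizontally (columns).
#' @param rot90_k Number of counter-clockwise 90-degree rotations (0-3).
#' @param rot_degrees Additional arbitrary rotation angle (0 = none).
#' @return List with transformed `image` and `mask`.
#' @export
apply_augment <- function(image, mask, flip_v = FALSE, flip_h = FALSE,
                          rot90_k = 0, rot_degrees = 0) {
  if (is.null(dim(image)) || length(dim(image)) == 2L)
    image <- array(image, c(dim(as.matrix(image)), 1L))
  tf_plane <- function(p, interp) {
    if (flip_v) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    if (flip_h) p <- p[, rev(seq_len(ncol(p))), drop = FALSE]
    k <- rot90_k %% 4
    for (i in seq_len(k)) p <- t(p)[rev(seq_len(ncol(p))), , drop = FALSE]
    if (rot_degrees %% 360 != 0) {
      if (nrow(p) != ncol(p))
        stop("arbitrary-angle rotation requires a square image")
      p <- rotate_plane(p, rot_degrees, interp)
    }
    p
  }
  img_out <- NULL
  for (ch in seq_len(dim(image)[3])) {
    plane <- tf_plane(image[, , ch], "bilinear")
    if (is.null(img_out))
      img_out <- array(0, c(dim(plane), dim(image)[3]))
    img_out[, , ch] <- plane
  }
  mask_out <- tf_plane(matrix(as.numeric(mask), nrow(mask)), "nearest")
  list(image = img_out, mask = matrix(as.integer(mask_out != 0), nrow(mask_out)))
}

#' Randomized augmentation of an image/mask pair
#'
#' Draws the transform parameters from a seeded generator: enabled flips are
#' applied with probability 1/2 each, `"rot90"` draws k uniformly from 0-3,
#' and `"rotate"` draws an angle uniformly from `rot_range`.
#'
#' @param image,mask As in [apply_augment()].
#' @param ops Character vector from `"flip_v"`, `"flip_h"`, `"rot90"`,
#'   `"rotate"`.
#' @param rot_range Angle range for `"rotate"`, default `c(0, 360)`.
#' @param seed Integer seed.
#' @return List with `image`, `mask` and the drawn `params`.
#' @export
augment <- function(image, mask, ops = c("flip_v", "flip_h", "rot90"),
                    rot_range = c(0, 360), seed = 1L) {
  known <- c("flip_v", "flip_h", "rot90", "rotate")
  bad <- setdiff(ops, known)
  if (length(bad) > 0L)
    stop(sprintf("unsupported augmentation op: %s", bad[1]))
  params <- with_seed(seed, list(
    flip_v = "flip_v" %in% ops && stats::runif(1) < 0.5,
    flip_h = "flip_h" %in% ops && stats::runif(1) < 0.5,
    rot90_k = if ("rot90" %in% ops) sample.int(4, 1) - 1L else 0L,
    rot_degrees = if ("rotate" %in% ops)
      stats::runif(1, rot_range[1], rot_range[2]) else 0))
  out <- apply_augment(image, mask, params$flip_v, params$flip_h,
                       params$rot90_k, params$rot_degrees)
  c(out, list(params = params))
}

#' Write a split assignment as a JSON manifest
#'
#' @param split A [split_by_unit()] result.
#' @param path Output path.
#' @export
split_to_json <- function(split, path) {
  obj <- list(fractions = split$fractions,
              counts = as.list(split$counts),
              assignment = split$assignment)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
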