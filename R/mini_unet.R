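# A deterministic, from-scratch U-Net-style forward engine.
#
# The point of this engine is not learned accuracy — weights are random but
# seeded — it is exact, reproducible forward geometry: shape arithmetic for
# padded ("same") and unpadded ("valid") convolutions, skip-connection
# alignment, and the translational variance introduced by max pooling.
# Everything is plain R on channels-last arrays; no deep-learning framework.

#' U-Net engine configuration
#'
#' @param ndim Spatial dimensionality, 2 or 3.
#' @param depth Number of max-pooling levels (>= 0); the cumulative stride of
#'   the encoder is `2^depth`, which governs both the input-divisibility
#'   requirement in same-padding mode and the shift multiples at which the
#'   network is translation-equivariant.
#' @param base_filters Feature channels at the first level; doubled per
#'   level.
#' @param in_channels Input image channels.
#' @param pad_mode `"same_zero"` (zero-padded convolutions preserve spatial
#'   size) or `"valid"` (no padding; each convolution shrinks every axis by
#'   `kernel - 1`).
#' @param kernel Odd convolution kernel size (default 3).
#' @param convs_per_block Convolutions per resolution level (default 2).
#' @param activation `"relu"` or `"leaky_relu"` (slope 0.01 on the negative
#'   side).
#' @param norm `"none"` or `"instance"` (per-channel standardization of the
#'   current input, epsilon 1e-5, applied after the activation).
#' @param seed Integer seed fixing every weight.
#' @return List of class `unet_config`.
#' @export
unet_config <- function(ndim = 2, depth = 4, base_filters = 16,
                        in_channels = 1, pad_mode = c("same_zero", "valid"),
                        kernel = 3, convs_per_block = 2,
                        activation = c("relu", "leaky_relu"),
                        norm = c("none", "instance"), seed = 1L) {
  pad_mode <- match.arg(pad_mode)
  activation <- match.arg(activation)
  norm <- match.arg(norm)
  if (!ndim %in% c(2, 3)) stop("ndim must be 2 or 3")
  if (depth < 0) stop("depth must be >= 0")
  if (kernel %% 2 != 1) stop("kernel must be odd")
  if (convs_per_block < 1) stop("convs_per_block must be >= 1")
  structure(list(ndim = as.integer(ndim), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 in_channels = as.integer(in_channels), pad_mode = pad_mode,
                 kernel = as.integer(kernel),
                 convs_per_block = as.integer(convs_per_block),
                 activation = activation, norm = norm,
                 seed = as.integer(seed)),
            class = "unet_config")
}

# ---- primitive layers -----------------------------------------------------

pad_spatial_zeros <- function(x, p, ndim) {
  dm <- dim(x)
  out <- array(0, dim = c(dm[seq_len(ndim)] + 2L * p, dm[-seq_len(ndim)]))
  idx <- c(lapply(dm[seq_len(ndim)], function(n) seq.int(p + 1L, p + n)),
           lapply(dm[-seq_len(ndim)], seq_len))
  do.call(`[<-`, c(list(out), idx, list(value = x)))
}

conv2d <- function(x, w, b, pad_mode) {
  k <- dim(w)[1]
  if (pad_mode == "same_zero" && k > 1L)
    x <- pad_spatial_zeros(x, (k - 1L) %/% 2L, 2L)
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  cout <- dim(w)[4]
  oh <- H - k + 1L; ow <- W - k + 1L
  if (oh < 1L || ow < 1L) stop("convolution input too small for kernel")
  cols <- matrix(0, oh * ow, k * k * cin)
  col <- 1L
  for (ci in seq_len(cin)) for (j in seq_len(k)) for (i in seq_len(k)) {
    cols[, col] <- x[i:(i + oh - 1L), j:(j + ow - 1L), ci]
    col <- col + 1L
  }
  out <- cols %*% matrix(w, k * k * cin, cout)
  out <- sweep(out, 2, b, `+`)
  array(out, c(oh, ow, cout))
}

conv3d <- function(x, w, b, pad_mode) {
  k <- dim(w)[1]
  if (pad_mode == "same_zero" && k > 1L)
    x <- pad_spatial_zeros(x, (k - 1L) %/% 2L, 3L)
  dm <- dim(x); cin <- dm[4]; cout <- dim(w)[5]
  os <- dm[1:3] - k + 1L
  if (any(os < 1L)) stop("convolution input too small for kernel")
  cols <- matrix(0, prod(os), k^3 * cin)
  col <- 1L
  for (ci in seq_len(cin)) for (l in seq_len(k)) for (j in seq_len(k))
    for (i in seq_len(k)) {
      cols[, col] <- x[i:(i + os[1] - 1L), j:(j + os[2] - 1L),
                       l:(l + os[3] - 1L), ci]
      col <- col + 1L
    }
  out <- cols %*% matrix(w, k^3 * cin, cout)
  out <- sweep(out, 2, b, `+`)
  array(out, c(os, cout))
}

conv_nd <- function(x, w, b, pad_mode, ndim) {
  if (ndim == 2L) conv2d(x, w, b, pad_mode) else conv3d(x, w, b, pad_mode)
}

apply_activation <- function(x, activation) {
  if (activation == "relu") pmax(x, 0)
  else pmax(x, 0) + 0.01 * pmin(x, 0)
}

instance_norm <- function(x, ndim, eps = 1e-5) {
  dm <- dim(x)
  nch <- dm[length(dm)]
  flat <- matrix(x, ncol = nch)
  mu <- colMeans(flat)
  v <- colMeans(sweep(flat, 2, mu, `-`)^2)
  flat <- sweep(sweep(flat, 2, mu, `-`), 2, sqrt(v + eps), `/`)
  array(flat, dm)
}

# channel-wise max pool, floor semantics (trailing remainder dropped)
maxpool_channels <- function(x, k, ndim) {
  dm <- dim(x)
  os <- dm[seq_len(ndim)] %/% k
  if (any(os < 1L)) stop("spatial dimension smaller than pool size")
  pick <- function(axis, phase)
    seq.int(phase, by = k, length.out = os[axis])
  phases <- expand.grid(rep(list(seq_len(k)), ndim))
  pieces <- lapply(seq_len(nrow(phases)), function(r) {
    idx <- lapply(seq_len(ndim), function(a) pick(a, phases[r, a]))
    idx <- c(idx, lapply(dm[-seq_len(ndim)], seq_len))
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  })
  Reduce(pmax, pieces)
}

#' Non-overlapping max pooling
#'
#' Partitions the input into `k`-sized windows (stride `k`) and takes the
#' maximum of each; trailing remainder rows/columns that do not fill a
#' window are dropped. Works on 1D vectors, 2D matrices and 3D arrays.
#'
#' @param x Numeric vector, matrix or 3D array (no channel axis).
#' @param k Pool size (default 2).
#' @return Pooled vector/matrix/array with each spatial dim `floor(dim/k)`.
#' @examples
#' maxpool(c(5, 1, 4, 2))  # c(5, 4)
#' @export
maxpool <- function(x, k = 2) {
  k <- as.integer(k)
  if (is.null(dim(x))) {
    n <- length(x) %/% k
    if (n < 1L) stop("input shorter than pool size")
    out <- Reduce(pmax, lapply(seq_len(k), function(ph)
      x[seq.int(ph, by = k, length.out = n)]))
    return(out)
  }
  ndim <- length(dim(x))
  dm <- dim(x)
  x <- array(x, c(dm, 1L))
  drop_channel(maxpool_channels(x, k, ndim))
}

upsample_nearest <- function(x, ndim, factor = 2L) {
  dm <- dim(x)
  idx <- c(lapply(dm[seq_len(ndim)], function(n)
    rep(seq_len(n), each = factor)),
    lapply(dm[-seq_len(ndim)], seq_len))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  nd <- length(da)
  if (!identical(da[-nd], db[-nd]))
    stop("cannot concatenate feature maps of different spatial shape")
  array(c(a, b), c(da[-nd], da[nd] + db[nd]))
}

# symmetric center crop of spatial dims to `target`; when the total crop on
# an axis is odd, the extra pixel is removed from the leading side
center_crop_spatial <- function(x, target, ndim) {
  dm <- dim(x)
  diffs <- dm[seq_len(ndim)] - target
  if (any(diffs < 0L)) stop("crop target larger than input")
  lead <- (diffs + 1L) %/% 2L
  idx <- c(lapply(seq_len(ndim), function(a)
    seq.int(lead[a] + 1L, lead[a] + target[a])),
    lapply(dm[-seq_len(ndim)], seq_len))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# ---- model construction ---------------------------------------------------

init_conv <- function(kdims, cin, cout) {
  fan_in <- prod(kdims) * cin
  a <- sqrt(3 / fan_in)
  list(w = array(stats::runif(prod(kdims) * cin * cout, -a, a),
                 dim = c(kdims, cin, cout)),
       b = rep(0, cout))
}

#' Build a seeded U-Net model
#'
#' Encoder (`convs_per_block` convolutions then 2x max pool per level),
#' bottleneck, decoder (nearest-neighbour x2 upsampling followed by a 1x1
#' channel-halving convolution, skip concatenation — center-cropped in valid
#' mode — and `convs_per_block` convolutions), and a 1x1 sigmoid head
#' producing a single-channel probability map. All weights are drawn from a
#' single seeded generator, uniform on `(-a, a)` with `a = sqrt(3 / fan_in)`
#' per layer and zero biases, so the same config always yields bit-identical
#' weights. The 1x1 up-convolution keeps the decoder free of additional
#' shrinkage so the valid-mode shape recurrence matches the classic
#' encoder-decoder arithmetic.
#'
#' @param config A [unet_config()].
#' @return List of class `unet_model` with `config` and `weights`.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  kd <- rep(config$kernel, config$ndim)
  one <- rep(1L, config$ndim)
  weights <- with_seed(config$seed, {
    w <- list(encoder = list(), bottleneck = NULL, decoder = list(),
              head = NULL)
    cin <- config$in_channels
    for (l in seq_len(config$depth)) {
      f <- config$base_filters * 2L^(l - 1L)
      convs <- list()
      for (i in seq_len(config$convs_per_block)) {
        convs[[i]] <- init_conv(kd, cin, f)
        cin <- f
      }
      w$encoder[[l]] <- list(convs = convs, filters = f)
    }
    fb <- config$base_filters * 2L^config$depth
    convs <- list()
    for (i in seq_len(config$convs_per_block)) {
      convs[[i]] <- init_conv(kd, cin, fb)
      cin <- fb
    }
    w$bottleneck <- list(convs = convs, filters = fb)
    for (l in rev(seq_len(config$depth))) {
      f <- config$base_filters * 2L^(l - 1L)
      up <- init_conv(one, cin, f)
      cin <- 2L * f  # after skip concatenation
      convs <- list()
      for (i in seq_len(config$convs_per_block)) {
        convs[[i]] <- init_conv(kd, cin, f)
        cin <- f
      }
      w$decoder[[length(w$decoder) + 1L]] <-
        list(up = up, convs = convs, filters = f)
    }
    w$head <- init_conv(one, cin, 1L)
    w
  })
  structure(list(config = config, weights = weights), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "unet_model: %dD, depth %d (stride %d), base %d, %s pad, kernel %d, seed %d\n",
    cfg$ndim, cfg$depth, 2L^cfg$depth, cfg$base_filters, cfg$pad_mode,
    cfg$kernel, cfg$seed))
  invisible(x)
}

#' Checksum of a model's weights
#'
#' @param model A `unet_model`.
#' @return Numeric summary (sum of all weight entries) plus parameter count
#'   as attribute `n_params`; equal for identically-seeded builds.
#' @export
unet_weight_checksum <- function(model) {
  flat <- unlist(model$weights, use.names = FALSE)
  structure(sum(flat), n_params = length(flat))
}

# ---- shape arithmetic -----------------------------------------------------

#' Validate an input shape against the model's shape rules
#'
#' The verdict is determined by walking the network's shape flow rather than
#' by a divisibility formula. For zero-padded models the walk requires every
#' spatial dimension to be even at each of the `depth` pooling steps (so the
#' upsampled decoder path re-aligns with the skip connections), which is
#' equivalent to divisibility by the cumulative stride `2^depth`; the
#' rejection reports that modulus. For valid-padding models the walk is the
#' full shrink/pool/upsample recurrence of [valid_output_shape()], and any
#' collapse to a non-positive size rejects.
#'
#' @param config A [unet_config()].
#' @param image_shape Integer vector of spatial dims (length `ndim`).
#' @return List with `accepted` (logical), and on rejection `modulus`
#'   (same-padding) or `reason`.
#' @export
validate_input_shape <- function(config, image_shape) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != config$ndim)
    return(list(accepted = FALSE,
                reason = sprintf("expected %d spatial dims, got %d",
                                 config$ndim, length(image_shape))))
  if (any(image_shape < 1L))
    return(list(accepted = FALSE, reason = "non-positive dimension"))
  if (config$pad_mode == "same_zero") {
    s <- image_shape
    for (l in seq_len(config$depth)) {
      if (any(s %% 2L != 0L)) {
        return(list(accepted = FALSE, modulus = as.integer(2^config$depth),
                    reason = sprintf(
                      "dimension %d not divisible at pooling level %d; input dims must be divisible by %d",
                      s[which(s %% 2L != 0L)[1]], l, 2L^config$depth)))
      }
      s <- s %/% 2L
      if (any(s < 1L))
        return(list(accepted = FALSE, modulus = as.integer(2^config$depth),
                    reason = "input too small for pooling depth"))
    }
    return(list(accepted = TRUE))
  }
  out <- tryCatch(valid_output_shape(config, image_shape),
                  error = function(e) e)
  if (inherits(out, "error"))
    return(list(accepted = FALSE, reason = conditionMessage(out)))
  list(accepted = TRUE, output_shape = out)
}

#' Output shape of a valid-padding model
#'
#' Evaluates the per-level recurrence of an unpadded encoder-decoder: each
#' convolution shrinks every axis by `kernel - 1`, pooling halves with floor,
#' upsampling doubles, the skip connection is center-cropped to match, and
#' the decoder convolutions shrink again. The classic depth-4 configuration
#' with two 3x3 convolutions per level maps 236 -> 52 and 572 -> 388 per
#' axis.
#'
#' @param config A [unet_config()] with `pad_mode = "valid"` (the recurrence
#'   is the identity for same-padding and is reported as such).
#' @param input_shape Integer vector of spatial dims.
#' @return Integer vector: the output spatial shape.
#' @export
valid_output_shape <- function(config, input_shape) {
  s <- as.integer(input_shape)
  if (config$pad_mode != "valid") return(s)
  shrink <- config$convs_per_block * (config$kernel - 1L)
  skips <- list()
  for (l in seq_len(config$depth)) {
    s <- s - shrink
    if (any(s < 1L))
      stop(sprintf("input too small: dimension collapses in encoder level %d convolutions", l))
    skips[[l]] <- s
    s <- s %/% 2L
    if (any(s < 1L))
      stop(sprintf("input too small: dimension collapses at pooling level %d", l))
  }
  s <- s - shrink
  if (any(s < 1L))
    stop("input too small: dimension collapses in bottleneck convolutions")
  for (l in rev(seq_len(config$depth))) {
    s <- s * 2L
    if (any(skips[[l]] < s))
      stop(sprintf("decoder level %d: skip connection smaller than upsampled map", l))
    s <- s - shrink
    if (any(s < 1L))
      stop(sprintf("input too small: dimension collapses in decoder level %d convolutions", l))
  }
  s
}

# ---- forward pass ---------------------------------------------------------

run_block <- function(x, convs, config) {
  for (cv in convs) {
    x <- conv_nd(x, cv$w, cv$b, config$pad_mode, config$ndim)
    x <- apply_activation(x, config$activation)
    if (config$norm == "instance") x <- instance_norm(x, config$ndim)
  }
  x
}

#' Forward pass of a U-Net model
#'
#' Pure deterministic function: the same model and input always produce the
#' same output. Output values are strictly inside (0, 1) (sigmoid head);
#' the output spatial shape equals the input shape in same-padding mode and
#' [valid_output_shape()] in valid mode.
#'
#' @param model A [build_unet()] model.
#' @param image Channels-last array `(H, W, C)` / `(H, W, D, C)`, or a plain
#'   matrix when `in_channels` is 1.
#' @return Probability map (matrix in 2D, array in 3D; no channel axis).
#' @export
unet_forward <- function(model, image) {
  cfg <- model$config
  if (is.null(dim(image)) || length(dim(image)) == cfg$ndim)
    image <- array(image, c(spatial_shape(image, cfg$ndim), 1L))
  dm <- dim(image)
  if (length(dm) != cfg$ndim + 1L || dm[length(dm)] != cfg$in_channels)
    stop(sprintf("expected %d input channel(s), got shape (%s)",
                 cfg$in_channels, paste(dm, collapse = ",")))
  verdict <- validate_input_shape(cfg, dm[seq_len(cfg$ndim)])
  if (!verdict$accepted)
    stop(sprintf("input shape rejected: %s", verdict$reason))
  x <- image
  skips <- list()
  for (l in seq_len(cfg$depth)) {
    x <- run_block(x, model$weights$encoder[[l]]$convs, cfg)
    skips[[l]] <- x
    x <- maxpool_channels(x, 2L, cfg$ndim)
  }
  x <- run_block(x, model$weights$bottleneck$convs, cfg)
  di <- 0L
  for (l in rev(seq_len(cfg$depth))) {
    di <- di + 1L
    dec <- model$weights$decoder[[di]]
    x <- upsample_nearest(x, cfg$ndim)
    x <- conv_nd(x, dec$up$w, dec$up$b, cfg$pad_mode, cfg$ndim)
    x <- apply_activation(x, cfg$activation)
    skip <- skips[[l]]
    if (cfg$pad_mode == "valid")
      skip <- center_crop_spatial(skip, dim(x)[seq_len(cfg$ndim)], cfg$ndim)
    x <- concat_channels(x, skip)
    x <- run_block(x, dec$convs, cfg)
  }
  x <- conv_nd(x, model$weights$head$w, model$weights$head$b,
               cfg$pad_mode, cfg$ndim)
  drop_channel(array(stats::plogis(x), dim = dim(x)))
}

#' Turn a model into a binary segmentation function
#'
#' @param model A `unet_model`.
#' @param threshold Binarization threshold (half-up), default 0.5.
#' @return `function(image)` returning an integer 0/1 mask.
#' @export
unet_predictor <- function(model, threshold = 0.5) {
  force(model); force(threshold)
  function(image) binarize(unet_forward(model, image), threshold)
}

# ---- the max-pooling window demonstration ---------------------------------

#' Two-window max-pooling demonstration
#'
#' The smallest exhibit of max pooling's translational variance: an 11 x 2
#' array admits exactly two 10 x 2 windows at unit stride (offsets 0 and 1).
#' Pooling each window 2x2 produces two 5 x 1 outputs which differ whenever
#' the input places a distinguishing value in the first row — the two
#' "identical up to translation" inputs yield different results.
#'
#' @param values Optional 11 x 2 input; the default is a ramp with a single
#'   large value at row 1.
#' @return List with `input`, `window_a`, `window_b` (the two 10 x 2
#'   windows), `pooled_a`, `pooled_b` (5 x 1 outputs) and `identical`.
#' @export
maxpool_window_demo <- function(values = NULL) {
  if (is.null(values)) {
    values <- matrix(seq_len(22) / 100, nrow = 11, ncol = 2)
    values[1, 1] <- 9
  }
  if (!identical(dim(values), c(11L, 2L))) stop("input must be 11 x 2")
  wa <- values[1:10, , drop = FALSE]
  wb <- values[2:11, , drop = FALSE]
  pa <- maxpool(wa, 2)
  pb <- maxpool(wb, 2)
  list(input = values, window_a = wa, window_b = wb,
       pooled_a = pa, pooled_b = pb,
       identical = identical(pa, pb))
}

# ---- serialization --------------------------------------------------------

#' Serialize a U-Net config to JSON (and back)
#'
#' @param config A [unet_config()].
#' @param path Optional output path.
#' @return JSON string.
#' @export
unet_config_to_json <- function(config, path = NULL) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname unet_config_to_json
#' @param x JSON string or file path.
#' @export
unet_config_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  do.call(unet_config, obj)
}

#' Export model weights to a flat binary container
#'
#' Writes one raw little-endian double file per weight tensor plus a JSON
#' manifest (name, shape, md5 checksum) for cross-run reproducibility
#' checks.
#'
#' @param model A `unet_model`.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
export_unet_weights <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in names(x)) {
        if (is.null(x[[nm]])) next
        walk(x[[nm]], paste0(prefix, ".", nm))
      }
      if (is.null(names(x)))
        for (i in seq_along(x)) walk(x[[i]], paste0(prefix, i))
    } else if (is.numeric(x)) {
      flat[[prefix]] <<- x
    }
  }
  walk(model$weights, "w")
  manifest <- lapply(names(flat), function(nm) {
    fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9]+", "_", nm), ".bin"))
    con <- file(fn, "wb")
    writeBin(as.double(flat[[nm]]), con, size = 8, endian = "little")
    close(con)
    list(name = nm, file = basename(fn),
         shape = if (is.null(dim(flat[[nm]]))) length(flat[[nm]])
         else dim(flat[[nm]]),
         md5 = unname(tools::md5sum(fn)))
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
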