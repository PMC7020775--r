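# Pixelwise Dice and instance-level polygon F1.
#
# Polygon coordinate frame: pixel (r, c) of a mask (1-based array indices)
# covers the unit square x in [c-1, c], y in [r-1, r]. Vertices therefore sit
# on the integer lattice and polygon area equals covered pixel area. Outer
# rings are stored with positive shoelace area, holes with negative area.

#' Pixel confusion counts between two binary masks
#'
#' @param pred,gt Integer 0/1 arrays of identical shape.
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("pred and gt must have identical shapes")
  p <- as.integer(pred) != 0L
  g <- as.integer(gt) != 0L
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 tn = sum(!p & !g), fn = sum(!p & g)),
            class = "confusion_counts")
}

#' Dice similarity coefficient
#'
#' `2 * TP / (2 * TP + FP + FN)` between two binary masks. When both masks
#' are empty the score is defined as 1 (the convention used in brain-tumor
#' segmentation benchmarking, where an empty prediction of an empty truth is
#' a perfect answer).
#'
#' @inheritParams confusion_counts
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  denom <- 2 * cc$tp + cc$fp + cc$fn
  if (denom == 0) return(1)
  2 * cc$tp / denom
}

# ---- connected components -------------------------------------------------

#' Label connected foreground components of a 2D mask
#'
#' Minimum-label propagation; deterministic labels renumbered 1..n in
#' raster order of each component's first pixel.
#'
#' @param mask Integer 0/1 matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return Integer matrix of labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 4) {
  if (length(dim(mask)) != 2L) stop("mask must be 2D")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask != 0L
  lab <- matrix(0L, h, w)
  lab[fg] <- seq_len(h * w)[fg]
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  repeat {
    changed <- FALSE
    for (s in shifts) {
      shifted <- matrix(0L, h, w)
      r_src <- seq_len(h) - s[1]; c_src <- seq_len(w) - s[2]
      r_ok <- r_src >= 1L & r_src <= h; c_ok <- c_src >= 1L & c_src <= w
      shifted[r_ok, c_ok] <- lab[r_src[r_ok], c_src[c_ok], drop = FALSE]
      upd <- fg & shifted > 0L & (shifted < lab)
      if (any(upd)) {
        lab[upd] <- shifted[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # renumber deterministically
  ids <- unique(lab[lab > 0L])
  if (length(ids) > 0L) {
    ids <- ids[order(match(ids, lab))]
    lab[lab > 0L] <- match(lab[lab > 0L], ids)
  }
  lab
}

# ---- polygon primitives ---------------------------------------------------

ring_area <- function(ring) {
  # signed shoelace area; ring is an n x 2 matrix (x, y), not closed
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

close_ring <- function(ring) rbind(ring, ring[1, , drop = FALSE])

#' Construct a polygon from an outer ring and optional holes
#'
#' Rings are `n x 2` matrices of (x, y) vertices in pixel coordinates,
#' not closed (first vertex not repeated). Orientation is normalized: the
#' outer ring to positive signed area, holes to negative, so the polygon
#' area is the plain sum of signed ring areas.
#'
#' @param outer Outer ring matrix.
#' @param holes Optional list of hole rings.
#' @return List of class `mask_polygon` with `rings` (outer first) and
#'   `area`.
#' @export
mask_polygon <- function(outer, holes = list()) {
  outer <- as.matrix(outer)
  if (ring_area(outer) < 0) outer <- outer[rev(seq_len(nrow(outer))), ]
  holes <- lapply(holes, function(hh) {
    hh <- as.matrix(hh)
    if (ring_area(hh) > 0) hh <- hh[rev(seq_len(nrow(hh))), ]
    hh
  })
  new_polygon(c(list(outer), holes))
}

# rings already oriented (positive = filled, negative = hole); a polygon may
# carry several positive rings when a component pinches at a corner
new_polygon <- function(rings) {
  area <- sum(vapply(rings, ring_area, numeric(1)))
  if (area <= 0) stop("polygon area must be positive")
  structure(list(rings = rings, area = area), class = "mask_polygon")
}

#' Construct a polygon set
#'
#' @param polygons List of [mask_polygon()] objects.
#' @return List of class `polygon_set`.
#' @export
polygon_set <- function(polygons = list()) {
  structure(list(polygons = polygons), class = "polygon_set")
}

#' @export
length.polygon_set <- function(x) length(x$polygons)

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("polygon_set: %d polygon(s), total area %g\n",
              length(x$polygons),
              sum(vapply(x$polygons, function(p) p$area, numeric(1)))))
  invisible(x)
}

poly_bbox <- function(p) {
  v <- do.call(rbind, p$rings)
  c(min(v[, 1]), min(v[, 2]), max(v[, 1]), max(v[, 2]))
}

# even-odd point-in-ring test, vectorized over points
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

points_in_polygon <- function(px, py, p) {
  inside <- rep(FALSE, length(px))
  for (ring in p$rings) inside <- xor(inside, points_in_ring(px, py, ring))
  inside
}

is_rectilinear <- function(ring) {
  cl <- close_ring(ring)
  dx <- diff(cl[, 1]); dy <- diff(cl[, 2])
  all(dx == 0 | dy == 0)
}

is_convex_ring <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  cl <- rbind(ring, ring[1:2, , drop = FALSE])
  cr <- numeric(n)
  for (i in seq_len(n)) {
    a <- cl[i + 1, ] - cl[i, ]
    b <- cl[i + 2, ] - cl[i + 1, ]
    cr[i] <- a[1] * b[2] - a[2] * b[1]
  }
  all(cr >= -1e-12) || all(cr <= 1e-12)
}

# Sutherland-Hodgman: clip subject ring by a convex clip ring (positive
# orientation); returns clipped ring matrix (possibly 0 rows)
clip_ring_convex <- function(subject, clip) {
  if (ring_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject
  nclip <- nrow(clip)
  for (i in seq_len(nclip)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]
    b <- clip[if (i == nclip) 1L else i + 1L, ]
    input <- out
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(input)
    side <- (b[1] - a[1]) * (input[, 2] - a[2]) -
      (b[2] - a[2]) * (input[, 1] - a[1])
    for (k in seq_len(n)) {
      kn <- if (k == n) 1L else k + 1L
      cur_in <- side[k] >= -1e-12
      nxt_in <- side[kn] >= -1e-12
      if (cur_in) out <- rbind(out, input[k, ])
      if (cur_in != nxt_in) {
        t <- side[k] / (side[k] - side[kn])
        out <- rbind(out, input[k, ] + t * (input[kn, ] - input[k, ]))
      }
    }
  }
  out
}

# exact intersection area of two rectilinear rings via grid decomposition
rect_ring_intersection_area <- function(r1, r2) {
  xs <- sort(unique(c(r1[, 1], r2[, 1])))
  ys <- sort(unique(c(r1[, 2], r2[, 2])))
  lo_x <- max(min(r1[, 1]), min(r2[, 1])); hi_x <- min(max(r1[, 1]), max(r2[, 1]))
  lo_y <- max(min(r1[, 2]), min(r2[, 2])); hi_y <- min(max(r1[, 2]), max(r2[, 2]))
  if (hi_x <= lo_x || hi_y <= lo_y) return(0)
  xs <- xs[xs >= lo_x & xs <= hi_x]
  ys <- ys[ys >= lo_y & ys <= hi_y]
  if (length(xs) < 2L || length(ys) < 2L) return(0)
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  wx <- diff(xs); wy <- diff(ys)
  grid <- expand.grid(ix = seq_along(cx), iy = seq_along(cy))
  px <- cx[grid$ix]; py <- cy[grid$iy]
  in_both <- points_in_ring(px, py, r1) & points_in_ring(px, py, r2)
  sum(wx[grid$ix[in_both]] * wy[grid$iy[in_both]])
}

ring_intersection_area <- function(r1, r2, sample_res = 8L) {
  if (is_rectilinear(r1) && is_rectilinear(r2))
    return(rect_ring_intersection_area(r1, r2))
  if (is_convex_ring(r2)) {
    clipped <- clip_ring_convex(r1, r2)
    return(if (nrow(clipped) < 3L) 0 else abs(ring_area(clipped)))
  }
  if (is_convex_ring(r1)) {
    clipped <- clip_ring_convex(r2, r1)
    return(if (nrow(clipped) < 3L) 0 else abs(ring_area(clipped)))
  }
  # fallback: supersampled rasterization over the bbox intersection
  lo_x <- max(min(r1[, 1]), min(r2[, 1])); hi_x <- min(max(r1[, 1]), max(r2[, 1]))
  lo_y <- max(min(r1[, 2]), min(r2[, 2])); hi_y <- min(max(r1[, 2]), max(r2[, 2]))
  if (hi_x <= lo_x || hi_y <= lo_y) return(0)
  step <- 1 / sample_res
  gx <- seq(lo_x + step / 2, hi_x, by = step)
  gy <- seq(lo_y + step / 2, hi_y, by = step)
  grid <- expand.grid(x = gx, y = gy)
  in_both <- points_in_ring(grid$x, grid$y, r1) &
    points_in_ring(grid$x, grid$y, r2)
  sum(in_both) * step^2
}

#' Intersection-over-union of two polygons
#'
#' Exact for pairs of rectilinear polygons (grid decomposition) and for pairs
#' where one outer ring is convex (polygon clipping); other shapes fall back
#' to supersampled rasterization.
#'
#' @param a,b [mask_polygon()] objects.
#' @return IoU in `[0, 1]`.
#' @export
polygon_iou <- function(a, b) {
  bba <- poly_bbox(a); bbb <- poly_bbox(b)
  if (bba[3] <= bbb[1] || bbb[3] <= bba[1] ||
      bba[4] <= bbb[2] || bbb[4] <= bba[2]) return(0)
  inter_rings <- function(rings_a, rings_b) {
    # signed inclusion-exclusion over ring pairs (positive rings fill,
    # negative rings carve holes; holes are nested inside their outers)
    total <- 0
    for (ra in rings_a) for (rb in rings_b) {
      sgn <- sign(ring_area(ra)) * sign(ring_area(rb))
      total <- total + sgn * ring_intersection_area(ra, rb)
    }
    total
  }
  inter <- inter_rings(a$rings, b$rings)
  union <- a$area + b$area - inter
  if (union <= 0) return(0)
  max(0, min(1, inter / union))
}

# ---- polygonization -------------------------------------------------------

# trace boundary rings of one labelled component; returns list of rings
trace_component <- function(comp) {
  # comp: logical matrix, TRUE = pixel belongs to component
  h <- nrow(comp); w <- ncol(comp)
  idx <- which(comp, arr.ind = TRUE)
  # directed boundary edges, one row per edge:
  # start (x,y), end (x,y), owning pixel id
  edges <- vector("list", 4L)
  r <- idx[, 1]; c <- idx[, 2]
  pid <- (c - 1L) * h + r
  at <- function(rr, cc) {
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    res <- rep(FALSE, length(rr))
    res[ok] <- comp[cbind(rr[ok], cc[ok])]
    res
  }
  up_bg <- !at(r - 1L, c); right_bg <- !at(r, c + 1L)
  down_bg <- !at(r + 1L, c); left_bg <- !at(r, c - 1L)
  # pixel corners: TL (c-1, r-1), TR (c, r-1), BR (c, r), BL (c-1, r)
  edges[[1]] <- cbind(c - 1L, r - 1L, c, r - 1L, pid)[up_bg, , drop = FALSE]
  edges[[2]] <- cbind(c, r - 1L, c, r, pid)[right_bg, , drop = FALSE]
  edges[[3]] <- cbind(c, r, c - 1L, r, pid)[down_bg, , drop = FALSE]
  edges[[4]] <- cbind(c - 1L, r, c - 1L, r - 1L, pid)[left_bg, , drop = FALSE]
  E <- do.call(rbind, edges)
  n_edges <- nrow(E)
  key <- function(x, y) paste(x, y)
  start_key <- key(E[, 1], E[, 2])
  by_start <- split(seq_len(n_edges), start_key)
  used <- rep(FALSE, n_edges)
  rings <- list()
  order_edges <- order(E[, 2], E[, 1], E[, 4], E[, 3])
  for (e0 in order_edges) {
    if (used[e0]) next
    ring <- matrix(NA_real_, n_edges + 1L, 2)
    ring[1, ] <- E[e0, 1:2]
    cur <- e0
    len <- 1L
    repeat {
      used[cur] <- TRUE
      len <- len + 1L
      ring[len, ] <- E[cur, 3:4]
      if (all(E[cur, 3:4] == E[e0, 1:2])) break
      cand <- by_start[[key(E[cur, 3], E[cur, 4])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) stop("boundary tracing failed to close a ring")
      if (length(cand) > 1L) {
        same_pix <- cand[E[cand, 5] == E[cur, 5]]
        cand <- if (length(same_pix) > 0L) same_pix else cand
      }
      cur <- cand[1]
    }
    ring <- ring[seq_len(len - 1L), , drop = FALSE]  # drop closing vertex
    # merge collinear consecutive edges
    keep <- rep(TRUE, nrow(ring))
    n <- nrow(ring)
    for (i in seq_len(n)) {
      prev <- ring[if (i == 1L) n else i - 1L, ]
      nxt <- ring[if (i == n) 1L else i + 1L, ]
      d1 <- ring[i, ] - prev; d2 <- nxt - ring[i, ]
      if (d1[1] * d2[2] - d1[2] * d2[1] == 0) keep[i] <- FALSE
    }
    rings[[length(rings) + 1L]] <- ring[keep, , drop = FALSE]
  }
  rings
}

#' Polygonize a binary mask
#'
#' Traces the pixel-boundary outline of every foreground connected component
#' (4-connectivity by default: pixels touching only diagonally form separate
#' components). Vertices lie on the integer lattice between pixels, so each
#' polygon's area equals its component's pixel count; interior holes are kept
#' as negatively-oriented rings and subtract from the area.
#'
#' @param mask Integer 0/1 matrix.
#' @param connectivity 4 or 8, passed to [label_components()].
#' @return A [polygon_set()], one polygon per component, ordered by the
#'   raster position of each component's first pixel.
#' @export
polygonize <- function(mask, connectivity = 4) {
  if (length(dim(mask)) != 2L) stop("mask must be 2D")
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  polys <- vector("list", n)
  for (k in seq_len(n)) {
    rings <- trace_component(lab == k)
    rings <- rings[order(-vapply(rings, ring_area, numeric(1)))]
    polys[[k]] <- new_polygon(rings)
  }
  polygon_set(polys)
}

#' Rasterize a polygon set to a binary mask
#'
#' A pixel is foreground when its center lies inside any polygon (even-odd
#' rule, so holes are carved out). Exact inverse of [polygonize()] for
#' integer-vertex rectilinear polygons.
#'
#' @param polyset A [polygon_set()].
#' @param shape `c(H, W)` of the output mask.
#' @return Integer 0/1 matrix.
#' @export
rasterize_polygons <- function(polyset, shape) {
  h <- shape[1]; w <- shape[2]
  mask <- matrix(0L, h, w)
  for (p in polyset$polygons) {
    bb <- poly_bbox(p)
    cols <- seq.int(max(1L, floor(bb[1]) + 1L), min(w, ceiling(bb[3])))
    rows <- seq.int(max(1L, floor(bb[2]) + 1L), min(h, ceiling(bb[4])))
    if (length(cols) == 0L || length(rows) == 0L) next
    grid <- expand.grid(r = rows, c = cols)
    inside <- points_in_polygon(grid$c - 0.5, grid$r - 0.5, p)
    mask[cbind(grid$r[inside], grid$c[inside])] <- 1L
  }
  mask
}

# ---- polygon matching -----------------------------------------------------

#' Instance-level polygon F1 (building-footprint style)
#'
#' Proposal and ground-truth polygons are matched greedily one-to-one in
#' descending IoU order; a pair counts as a true positive when its IoU is
#' strictly above `iou_threshold`. Precision, recall and their harmonic mean
#' are computed over the match counts. This is the instance metric that
#' penalizes merged or missed object instances which pixelwise Dice ignores.
#'
#' @param proposals,ground_truth [polygon_set()] objects.
#' @param iou_threshold Strict lower bound for a true-positive match
#'   (default 0.5).
#' @return List of class `match_result` with `tp`, `fp`, `fn`, `pairs`
#'   (data.frame: proposal, ground_truth, iou), `precision`, `recall`, `f1`.
#' @export
polygon_f1 <- function(proposals, ground_truth, iou_threshold = 0.5) {
  np <- length(proposals$polygons)
  ng <- length(ground_truth$polygons)
  cand <- list()
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    iou <- polygon_iou(proposals$polygons[[i]], ground_truth$polygons[[j]])
    if (iou > iou_threshold)
      cand[[length(cand) + 1L]] <- c(i, j, iou)
  }
  pairs <- data.frame(proposal = integer(0), ground_truth = integer(0),
                      iou = numeric(0))
  if (length(cand) > 0L) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    used_p <- rep(FALSE, np); used_g <- rep(FALSE, ng)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_p[i] && !used_g[j]) {
        used_p[i] <- TRUE; used_g[j] <- TRUE
        pairs <- rbind(pairs, data.frame(proposal = i, ground_truth = j,
                                         iou = cand[k, 3]))
      }
    }
  }
  tp <- nrow(pairs)
  fp <- np - tp
  fn <- ng - tp
  precision <- if (np == 0L) 0 else tp / np
  recall <- if (ng == 0L) 0 else tp / ng
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, pairs = pairs,
                 precision = precision, recall = recall, f1 = f1),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("polygon match: TP %d, FP %d, FN %d | precision %.3f recall %.3f F1 %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

# ---- morphology -----------------------------------------------------------

#' Binary dilation of a 2D mask
#'
#' Repeated one-pixel dilation with a 3x3 square (8-neighbour) or plus-shaped
#' (4-neighbour) structuring element. Used e.g. to emulate merged object
#' instances when studying pixel vs instance metrics.
#'
#' @param mask Integer 0/1 matrix.
#' @param radius Number of dilation steps.
#' @param kernel `"square"` or `"plus"`.
#' @return Integer 0/1 matrix.
#' @export
dilate_mask <- function(mask, radius = 1, kernel = c("square", "plus")) {
  kernel <- match.arg(kernel)
  h <- nrow(mask); w <- ncol(mask)
  out <- mask != 0L
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (kernel == "square")
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  for (step in seq_len(radius)) {
    cur <- out
    for (s in shifts) {
      r_src <- seq_len(h) - s[1]; c_src <- seq_len(w) - s[2]
      r_ok <- r_src >= 1L & r_src <= h; c_ok <- c_src >= 1L & c_src <= w
      shifted <- matrix(FALSE, h, w)
      shifted[r_ok, c_ok] <- cur[r_src[r_ok], c_src[c_ok], drop = FALSE]
      out <- out | shifted
    }
  }
  matrix(as.integer(out), h, w)
}

# ---- GeoJSON --------------------------------------------------------------

#' Write a polygon set as GeoJSON
#'
#' Emits a FeatureCollection of Polygon features in pixel coordinates; an
#' optional affine map `(x, y) -> (a x + b y + tx, c x + d y + ty)` can be
#' applied on the way out (e.g. toward a geo-referenced frame).
#'
#' @param polyset A [polygon_set()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @param affine Optional list with `A` (2x2 matrix) and `t` (length-2
#'   translation).
#' @return JSON string, invisibly when written to file.
#' @export
polygons_to_geojson <- function(polyset, path = NULL, affine = NULL) {
  feats <- lapply(polyset$polygons, function(p) {
    coords <- lapply(p$rings, function(ring) {
      if (!is.null(affine))
        ring <- sweep(ring %*% t(affine$A), 2, affine$t, `+`)
      unname(lapply(seq_len(nrow(ring) + 1L), function(i) {
        j <- if (i > nrow(ring)) 1L else i
        c(ring[j, 1], ring[j, 2])
      }))
    })
    list(type = "Feature", properties = list(area = p$area),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a polygon set from GeoJSON
#'
#' @param x File path or GeoJSON string with Polygon features.
#' @return A [polygon_set()].
#' @export
polygons_from_geojson <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  polys <- lapply(obj$features, function(f) {
    rings <- lapply(f$geometry$coordinates, function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ]))
        m <- m[-nrow(m), , drop = FALSE]
      m
    })
    mask_polygon(rings[[1]], rings[-1])
  })
  polygon_set(polys)
}
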