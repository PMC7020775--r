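small_scan_cfg <- function(seed = 1, n_blobs = 2) {
  scan_phantom_config(shape = c(40, 40, 20), channels = 4,
                      n_blobs = n_blobs, blob_radius = c(3, 6), seed = seed)
}

test_that("scan phantoms have the configured geometry and are seed-pure", {
  cfg <- small_scan_cfg()
  scan <- make_brats_like_scan(cfg)
  expect_identical(dim(scan$volume), c(40L, 40L, 20L, 4L))
  expect_identical(dim(scan$mask), c(40L, 40L, 20L))
  expect_gt(sum(scan$mask), 0)
  expect_true(all(scan$mask %in% c(0L, 1L)))
  expect_identical(scan, make_brats_like_scan(cfg))

  # zero outside the support ellipsoid: corners must be empty
  expect_equal(scan$volume[1, 1, 1, ], rep(0, 4))
  expect_equal(scan$volume[40, 40, 20, ], rep(0, 4))

  # blobless phantom -> empty mask
  empty <- make_brats_like_scan(small_scan_cfg(n_blobs = 0))
  expect_identical(sum(empty$mask), 0L)

  expect_error(scan_phantom_config(shape = c(30, 30, 10),
                                   blob_radius = c(4, 8)),
               "radius")
})

test_that("the default phantom configuration matches the scan geometry in use", {
  cfg <- scan_phantom_config()
  expect_identical(cfg$shape, c(240L, 240L, 155L))
  expect_identical(cfg$channels, 4L)
})

test_that("preprocessing clips, z-scores non-zero voxels, and keeps zeros zero", {
  scan <- make_brats_like_scan(small_scan_cfg(seed = 3))
  norm <- preprocess_scan(scan$volume)
  for (ch in 1:4) {
    v <- norm[, , , ch]
    nz <- v != 0
    expect_lt(abs(mean(v[nz])), 1e-6)
    expect_lt(abs(stats::sd(v[nz]) - 1), 1e-6)
    expect_true(all(v[scan$volume[, , , ch] == 0] == 0))
  }

  # an extreme outlier is clipped to the 98th-percentile value first
  vol <- array(stats::rnorm(1000, mean = 5), c(10, 10, 10, 1))
  vol[1, 1, 1, 1] <- 1e6
  q <- stats::quantile(vol[, , , 1], 0.98, names = FALSE)
  out <- preprocess_scan(vol)
  clipped <- pmin(vol[, , , 1], q)
  expect_equal(out[1, 1, 1, 1], max(out[, , , 1]))
  expect_equal(out[, , , 1],
               (clipped - mean(clipped)) / stats::sd(clipped),
               tolerance = 1e-12)

  # an all-zero channel is left untouched, with a warning
  vol0 <- array(0, c(4, 4, 4, 2)); vol0[, , , 1] <- stats::rnorm(64)
  expect_warning(out0 <- preprocess_scan(vol0), "channel 2")
  expect_identical(out0[, , , 2], array(0, c(4, 4, 4)))
})

test_that("preprocessing is idempotent when no values sit above the clip point", {
  # tie the top 3% so the 98th-percentile clip is inactive, and use no zeros
  set.seed(8)
  v <- stats::rnorm(4000)
  cap <- stats::quantile(v, 0.97, names = FALSE)
  v[v > cap] <- cap
  vol <- array(v, c(20, 20, 10, 1))
  once <- preprocess_scan(vol)
  twice <- preprocess_scan(once)
  expect_lt(max(abs(twice - once)), 1e-6)
})

test_that("slicing yields one pair per plane and inverts stacking", {
  scan <- make_brats_like_scan(small_scan_cfg(seed = 5))
  pairs <- slice_scan(scan$volume, scan$mask)
  expect_length(pairs, 20)
  expect_identical(dim(pairs[[1]]$image), c(40L, 40L, 4L))
  expect_identical(dim(pairs[[1]]$mask), c(40L, 40L))
  restacked <- stack_slices(lapply(pairs, function(p) p$mask))
  expect_identical(restacked, scan$mask)

  one <- slice_scan(array(1, c(3, 3, 1, 2)), array(0L, c(3, 3, 1)))
  expect_length(one, 1)
  expect_error(slice_scan(scan$volume, scan$mask[, , 1:5]), "matching")
})

test_that("unit-level splits partition the units at the requested sizes", {
  sp <- split_by_unit(paste0("scan", 1:335), c(270, 30, 35) / 335, seed = 4)
  expect_identical(sp$counts,
                   c(train = 270L, validation = 30L, test = 35L))
  expect_identical(sort(sp$assignment$unit), sort(paste0("scan", 1:335)))
  expect_false(anyDuplicated(sp$assignment$unit) > 0)

  sp10 <- split_by_unit(letters[1:10], c(0.7, 0.2, 0.1), seed = 1)
  expect_identical(unname(sp10$counts), c(7L, 2L, 1L))

  # no unit in two splits, by construction: one row per unit
  expect_identical(nrow(sp10$assignment), 10L)
  expect_identical(sum(sp10$assignment$split == "train"), 7L)
  expect_error(split_by_unit(c("a", "a"), c(0.7, 0.2, 0.1)), "unique")
  expect_error(split_by_unit(letters[1:5], c(0.5, 0.4, 0.2)), "sum")

  f <- tempfile(fileext = ".json")
  split_to_json(sp10, f)
  obj <- jsonlite::fromJSON(f)
  expect_identical(obj$counts$train, 7L)
})

test_that("building scenes carry exact vector ground truth", {
  cfg <- scene_config(image_size = c(150, 150), n_buildings = 6,
                      n_culdesacs = 1, size_range = c(12, 20),
                      min_gap = 6, seed = 9)
  sc <- make_building_scene(cfg)
  expect_identical(dim(sc$image), c(150L, 150L, 3L))
  expect_identical(dim(sc$mask), c(150L, 150L))
  expect_length(sc$polygons, 6 + 6)  # standalone + one 6-house cul-de-sac
  expect_identical(sc, make_building_scene(cfg))

  # gaps >= 1 pixel: polygonize recovers exactly the ground-truth count
  expect_length(polygonize(sc$mask), length(sc$polygons))
  expect_identical(rasterize_polygons(sc$polygons, c(150, 150)), sc$mask)
})

test_that("dilating a scene mask merges cul-de-sacs: Dice stays high, F1 drops", {
  sc <- make_building_scene(scene_config(
    image_size = c(150, 150), n_buildings = 5, n_culdesacs = 1,
    size_range = c(18, 28), min_gap = 8, culdesac_gap = 3, seed = 7))
  clean <- polygon_f1(polygonize(sc$mask), sc$polygons)
  expect_equal(clean$f1, 1)

  dil <- dilate_mask(sc$mask, 2)
  merged <- polygon_f1(polygonize(dil), sc$polygons)
  expect_gt(dice(dil, sc$mask), 0.75)
  expect_lt(merged$f1, clean$f1 - 0.25)
  expect_lt(length(polygonize(dil)), length(sc$polygons))
})

test_that("rotated building scenes stay consistent between mask and polygons", {
  cfg <- scene_config(image_size = c(120, 120), n_buildings = 4,
                      n_culdesacs = 0, size_range = c(14, 22),
                      min_gap = 8, rotation_range = c(10, 80), seed = 3)
  sc <- make_building_scene(cfg)
  expect_length(sc$polygons, 4)
  # rasterized mask pixel count close to summed polygon area
  area <- sum(vapply(sc$polygons$polygons, function(p) p$area, numeric(1)))
  expect_lt(abs(sum(sc$mask) - area) / area, 0.15)
})

test_that("augmentation transforms image and mask together and invertibly", {
  set.seed(10)
  img <- array(runif(24 * 24 * 2), c(24, 24, 2))
  msk <- matrix(rbinom(24 * 24, 1, 0.3), 24, 24)

  a <- apply_augment(img, msk, flip_v = TRUE)
  b <- apply_augment(a$image, a$mask, flip_v = TRUE)
  expect_identical(b$image, img)
  expect_identical(b$mask, msk)

  r <- list(image = img, mask = msk)
  for (i in 1:4) r <- apply_augment(r$image, r$mask, rot90_k = 1)
  expect_identical(r$image, img)
  expect_identical(r$mask, msk)

  # pixel-count preservation under flips and rot90
  for (tf in list(apply_augment(img, msk, flip_h = TRUE),
                  apply_augment(img, msk, rot90_k = 3))) {
    expect_identical(sum(tf$mask), sum(msk))
  }

  rot <- apply_augment(img, msk, rot_degrees = 37)
  expect_true(all(rot$mask %in% c(0L, 1L)))
  expect_identical(dim(rot$image), dim(img))

  rnd <- augment(img, msk, ops = c("flip_v", "rot90"), seed = 2)
  expect_identical(rnd, augment(img, msk, ops = c("flip_v", "rot90"),
                                seed = 2))
  expect_error(augment(img, msk, ops = "zoom"), "unsupported")
})
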