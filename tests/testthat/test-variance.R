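test_that("trinary diff codes and counts match a per-pixel oracle", {
  a <- matrix(0L, 3, 3); b <- a
  expect_identical(trinary_diff(a, b)$counts[["agree"]], 9L)

  a1 <- a; a1[2, 2] <- 1L
  d <- trinary_diff(a1, a)
  expect_identical(d$counts[["only_a"]], 1L)
  expect_identical(d$counts[["only_b"]], 0L)
  expect_identical(d$codes[2, 2], 1L)

  set.seed(3)
  x <- matrix(rbinom(64, 1, 0.5), 8, 8)
  y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  d2 <- trinary_diff(x, y)
  expect_identical(d2$counts[["agree"]], sum(x == y))
  expect_identical(d2$counts[["only_a"]], sum(x == 1L & y == 0L))
  expect_identical(d2$counts[["only_b"]], sum(x == 0L & y == 1L))
  expect_identical(sum(d2$counts), 64L)
  expect_error(trinary_diff(x, matrix(0L, 4, 4)), "shape")
})

test_that("an equivariant pointwise predictor has zero flip variance", {
  sl <- blob_slice(seed = 2)
  fr <- flip_variance(pointwise_predictor(level = 1.5), sl$image, sl$mask, 1)
  expect_equal(fr$cross_dice, 1)
  expect_identical(fr$diff$counts[["only_a"]] + fr$diff$counts[["only_b"]], 0L)

  # empty ground truth, both predictions empty
  img0 <- array(0, c(16, 16, 1))
  fr0 <- flip_variance(function(im) binarize(im[, , 1], 0.5),
                       img0, matrix(0L, 16, 16), 2)
  expect_equal(fr0$dice_normal, 1)
  expect_equal(fr0$dice_flipped, 1)
  expect_equal(fr0$cross_dice, 1)
})

test_that("flip-symmetric image and truth give equal normal and flipped Dice", {
  # null case that holds for any deterministic predictor: when both image
  # and ground truth are invariant under the flip, the flipped-input
  # prediction scores exactly the same Dice as the normal one (the two
  # predictions themselves may still differ; that is the flip variance)
  m <- build_unet(unet_config(depth = 2, base_filters = 4, in_channels = 1,
                              seed = 31))
  set.seed(31)
  half <- matrix(runif(16 * 32), 16, 32)
  sym <- rbind(half, half[16:1, ])  # invariant under vertical flip
  gt_half <- matrix(rbinom(16 * 32, 1, 0.3), 16, 32)
  gt <- rbind(gt_half, gt_half[16:1, ])
  fr <- flip_variance(unet_predictor(m), array(sym, c(32, 32, 1)), gt, 1)
  expect_equal(fr$dice_normal, fr$dice_flipped)
})

test_that("a seeded same-padded model flips with visible variance", {
  sl <- blob_slice(seed = 1)
  m <- build_unet(unet_config(depth = 2, base_filters = 4, in_channels = 4,
                              seed = 101))
  fr <- flip_variance(unet_predictor(m), sl$image, sl$mask, 1)
  expect_lt(fr$cross_dice, 1)
  expect_gt(sum(fr$diff$counts[c("only_a", "only_b")]), 0L)
})

test_that("flip disagreements of seeded models concentrate near the mask boundary", {
  # disagreement rate inside a 3-pixel band around the ground-truth
  # boundary vs outside it; the in-band rate should win for most seeds
  wins <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    sl <- blob_slice(seed = s)
    m <- build_unet(unet_config(depth = 2, base_filters = 4,
                                in_channels = 4, seed = s + 100))
    fr <- flip_variance(unet_predictor(m), sl$image, sl$mask, 1)
    bb <- fr$boundary_band
    if (!is.na(bb[["band_rate"]]) &&
        bb[["band_rate"]] > bb[["outside_rate"]]) wins <- wins + 1L
  }
  expect_gt(wins, n_seeds / 2)
})

test_that("translation variance enumerates the 24-offset grid and is zero for pointwise predictors", {
  sl <- blob_slice(seed = 4)
  tr <- translation_variance(pointwise_predictor(level = 1.5), sl$image,
                             c(32, 32), max_offset = 2)
  expect_length(tr$entries, 24)
  expect_true(all(vapply(tr$entries, function(e) e$cross_dice,
                         numeric(1)) == 1))
  expect_true(all(vapply(tr$entries, function(e)
    all(e$overlap_shape >= 30L), logical(1))))
  # offsets exclude the zero vector
  expect_false("0,0" %in% names(tr$entries))

  tr1 <- translation_variance(pointwise_predictor(level = 1.5), sl$image,
                              c(32, 32), max_offset = 1)
  expect_length(tr1$entries, 8)
})

test_that("a same-padded model shows single-pixel translation variance", {
  sl <- blob_slice(seed = 1)
  m <- build_unet(unet_config(depth = 2, base_filters = 4, in_channels = 4,
                              seed = 103))
  tr <- translation_variance(unet_predictor(m), sl$image, c(32, 32),
                             max_offset = 1)
  cds <- vapply(tr$entries, function(e) e$cross_dice, numeric(1))
  expect_lt(min(cds), 1)
})

test_that("valid conv+pool models are equivariant exactly at stride multiples", {
  # stride-2 model: one pooling level, no padding
  cfg <- unet_config(depth = 1, pad_mode = "valid", base_filters = 2,
                     in_channels = 1, seed = 12)
  m <- build_unet(cfg)
  sl <- blob_slice(seed = 6, shape = c(64, 64, 26))
  img <- array(sl$image[, , 1], c(64, 64, 1))
  offsets <- list(c(2, 0), c(0, 2), c(2, 2), c(-2, -2), c(4, 0))
  ck <- equivariance_check(unet_predictor(m), img, c(40, 40), offsets,
                           stride = 2)
  expect_true(ck$verdict)
  expect_true(all(ck$results$identical))

  # stride-1 model (no pooling, valid conv): every offset identical
  cfg0 <- unet_config(depth = 0, pad_mode = "valid", base_filters = 2,
                      in_channels = 1, seed = 13)
  m0 <- build_unet(cfg0)
  ck0 <- equivariance_check(unet_predictor(m0), img, c(40, 40),
                            list(c(1, 0), c(0, 1), c(1, 1), c(-1, 2)),
                            stride = 1)
  expect_true(all(ck0$results$identical))
})

test_that("three stacked 2x2 pools are equivariant exactly at multiples of 8", {
  search <- pool_stack_shift_search(n_layers = 3, strip_len = 64,
                                    max_shift = 16)
  expect_identical(search$shift[!search$differs], c(8L, 16L))
  expect_true(all(search$differs[c(1:7, 9:15)]))
  expect_identical(equivariant_stride(search), 8L)

  # one pooling layer restores equivariance at every even shift
  s1 <- pool_stack_shift_search(n_layers = 1, strip_len = 32, max_shift = 8)
  expect_identical(equivariant_stride(s1), 2L)
})

test_that("diff maps render as gray/white/black PNGs", {
  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  d <- trinary_diff(a, b)
  f <- tempfile(fileext = ".png")
  write_diff_png(d, f)
  img <- png::readPNG(f)
  expect_equal(img[1, 1], 1)          # only_a -> white
  expect_equal(img[4, 4], 0)          # only_b -> black
  expect_equal(img[2, 2], 128 / 255, tolerance = 1e-6)  # agree -> gray
})
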