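test_that("identically-seeded builds are bit-identical; different seeds differ", {
  cfg <- unet_config(depth = 2, base_filters = 4, in_channels = 3, seed = 42)
  m1 <- build_unet(cfg)
  m2 <- build_unet(cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(unet_weight_checksum(m1), unet_weight_checksum(m2))
  m3 <- build_unet(unet_config(depth = 2, base_filters = 4, in_channels = 3,
                               seed = 43))
  expect_false(identical(unet_weight_checksum(m1), unet_weight_checksum(m3)))
})

test_that("building a model does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(build_unet(unet_config(depth = 1, base_filters = 2)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("same-padding admissibility follows the pooling walk, not a lookup", {
  cfg4 <- unet_config(depth = 4)
  expect_true(validate_input_shape(cfg4, c(240, 240))$accepted)
  v650 <- validate_input_shape(unet_config(depth = 5), c(650, 650))
  expect_false(v650$accepted)
  expect_identical(v650$modulus, 32L)
  expect_true(validate_input_shape(unet_config(depth = 0), c(17, 3))$accepted)

  # the accepted set for depth 2 is exactly the multiples of 4, and the
  # verdict agrees with whether a real forward pass preserves the shape
  cfg2 <- unet_config(depth = 2, base_filters = 2)
  m2 <- build_unet(cfg2)
  for (n in 4:24) {
    verdict <- validate_input_shape(cfg2, c(n, n))$accepted
    expect_identical(verdict, n %% 4L == 0L)
    ran <- tryCatch({
      p <- unet_forward(m2, matrix(runif(n * n), n, n))
      identical(dim(p), c(n, n))
    }, error = function(e) FALSE)
    expect_identical(ran, verdict)
  }
})

test_that("valid-padding shape recurrence reproduces the classic arithmetic", {
  cfg <- unet_config(depth = 4, pad_mode = "valid")
  expect_identical(valid_output_shape(cfg, c(236, 236)), c(52L, 52L))
  expect_identical(valid_output_shape(cfg, c(572, 572)), c(388L, 388L))
  expect_error(valid_output_shape(cfg, c(20, 20)), "too small")

  # forward pass of a real valid-pad model matches the recurrence
  cfg2 <- unet_config(depth = 2, pad_mode = "valid", base_filters = 2,
                      seed = 6)
  m <- build_unet(cfg2)
  for (n in c(44, 60)) {
    p <- unet_forward(m, matrix(runif(n * n), n, n))
    expect_identical(dim(p), as.integer(valid_output_shape(cfg2, c(n, n))))
  }
})

test_that("maxpool takes window maxima with floor semantics", {
  expect_equal(maxpool(c(5, 1, 4, 2)), c(5, 4))
  expect_equal(maxpool(c(5, 1, 4, 2, 9)), c(5, 4))  # trailing 9 dropped
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  expect_equal(maxpool(m), matrix(5, 1, 1))
  expect_equal(maxpool(matrix(2, 6, 4)), matrix(2, 3, 2))
  a3 <- array(seq_len(4^3), c(4, 4, 4))
  expect_equal(dim(maxpool(a3)), c(2L, 2L, 2L))
  expect_error(maxpool(c(1)), "shorter")
})

test_that("the 11x2 array admits two 10x2 windows whose pooled outputs differ", {
  demo <- maxpool_window_demo()
  expect_identical(dim(demo$window_a), c(10L, 2L))
  expect_identical(dim(demo$window_b), c(10L, 2L))
  expect_identical(dim(demo$pooled_a), c(5L, 1L))
  expect_identical(dim(demo$pooled_b), c(5L, 1L))
  expect_false(demo$identical)
  # a constant input cannot distinguish the windows
  const <- maxpool_window_demo(matrix(1, 11, 2))
  expect_true(const$identical)
})

test_that("forward output is a deterministic probability map of the right shape", {
  m <- build_unet(unet_config(depth = 2, base_filters = 4, in_channels = 2,
                              seed = 7))
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  p1 <- unet_forward(m, x)
  p2 <- unet_forward(m, x)
  expect_identical(p1, p2)
  expect_identical(dim(p1), c(32L, 32L))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(unet_forward(m, matrix(0, 30, 30)), "rejected|channel")
  expect_error(unet_forward(m, array(0, c(32, 32, 3))), "channel")
})

test_that("a depth-0 kernel-1 model is pointwise: tiling cannot change it", {
  m <- build_unet(unet_config(depth = 0, kernel = 1, base_filters = 4,
                              in_channels = 1, seed = 3))
  img <- matrix(runif(40 * 40), 40, 40)
  whole <- unet_forward(m, img)
  for (layout in list(corner_center_layout(c(40, 40), c(24, 24)),
                      sliding_window_layout(c(40, 40), c(16, 16), 0.5))) {
    for (t in layout$tiles) {
      tile_p <- unet_forward(m, extract_tile(img, t))
      expect_identical(tile_p,
                       extract_tile(whole, t))
    }
  }
})

test_that("valid-padding models are shift-equivariant at multiples of the stride", {
  # depth d, no padding: shifting the input by 2^d shifts the output by 1
  for (d in 0:2) {
    cfg <- unet_config(depth = d, pad_mode = "valid", base_filters = 2,
                       seed = 20 + d)
    m <- build_unet(cfg)
    stride <- 2L^d
    n <- switch(as.character(d), "0" = 16L, "1" = 28L, "2" = 48L)
    big <- matrix(runif((n + 2 * stride)^2), n + 2 * stride)
    p_base <- unet_forward(m, big[1:n, 1:n])
    p_shift <- unet_forward(m, big[(1 + stride):(n + stride),
                                   (1 + stride):(n + stride)])
    # the output grid has unit stride, so content shifts by the full stride
    out_shift <- stride
    os <- dim(p_base)[1]
    expect_equal(p_base[(1 + out_shift):os, (1 + out_shift):os],
                 p_shift[1:(os - out_shift), 1:(os - out_shift)],
                 tolerance = 1e-12)
  }
})

test_that("instance norm and leaky relu variants run and stay deterministic", {
  cfg <- unet_config(depth = 1, base_filters = 4, in_channels = 2,
                     activation = "leaky_relu", norm = "instance", seed = 5)
  m <- build_unet(cfg)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  p <- unet_forward(m, x)
  expect_identical(p, unet_forward(m, x))
  expect_true(all(p > 0 & p < 1))
})

test_that("a 3D model forwards with the same shape rules", {
  cfg <- unet_config(ndim = 3, depth = 1, base_filters = 2, in_channels = 1,
                     seed = 2)
  m <- build_unet(cfg)
  x <- array(runif(8 * 8 * 8), c(8, 8, 8, 1))
  p <- unet_forward(m, x)
  expect_identical(dim(p), c(8L, 8L, 8L))
  expect_true(all(p > 0 & p < 1))
  expect_false(validate_input_shape(cfg, c(8, 8, 7))$accepted)
})

test_that("config JSON and weight export round-trip", {
  cfg <- unet_config(depth = 3, pad_mode = "valid", base_filters = 8,
                     in_channels = 4, activation = "leaky_relu", seed = 77)
  expect_identical(unet_config_from_json(unet_config_to_json(cfg)), cfg)

  m <- build_unet(unet_config(depth = 1, base_filters = 2, seed = 8))
  d <- tempfile()
  man <- export_unet_weights(m, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_true(all(vapply(man, function(e)
    file.exists(file.path(d, e$file)), logical(1))))
  # re-export of the same seeded model yields identical checksums
  d2 <- tempfile()
  man2 <- export_unet_weights(build_unet(unet_config(depth = 1,
                                                     base_filters = 2,
                                                     seed = 8)), d2)
  expect_identical(vapply(man, function(e) e$md5, character(1)),
                   vapply(man2, function(e) e$md5, character(1)))
})
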