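test_that("channel depths follow base * growth^(l-1), including the full-scale preset", {
  cfg <- encoder_config(levels = 4L, base_channels = 64L, preset = "paper")
  expect_identical(cfg$channels, c(64L, 128L, 256L, 512L))
  tiny <- encoder_config(levels = 4L, base_channels = 8L)
  expect_identical(tiny$channels, c(8L, 16L, 32L, 64L))
  expect_error(encoder_config(kernel_size = 4L), "odd")
  expect_error(encoder_config(levels = 0L), "levels")
})

test_that("encoder parameters are bit-identical under the same seed", {
  cfg <- encoder_config(levels = 3L, base_channels = 4L)
  e1 <- build_encoder(cfg, seed = 9L)
  e2 <- build_encoder(cfg, seed = 9L)
  for (nm in names(e1$params)) {
    expect_identical(e1$params[[nm]]$value, e2$params[[nm]]$value)
  }
  e3 <- build_encoder(cfg, seed = 10L)
  expect_false(identical(e1$params$conv1_w$value, e3$params$conv1_w$value))
})

test_that("parameter count matches the closed-form conv + norm count", {
  # L = 2, base = 1, growth 2, kernel 3, single-channel input:
  # block 1: conv 3x3x1 -> 1 (9 w + 1 b) + BN (gamma, beta: 2)
  # between: stride-2 conv 3x3x1 -> 2 (18 w + 2 b)
  # block 2: conv 3x3x2 -> 2 (36 w + 2 b) + BN (4)
  cfg <- encoder_config(levels = 2L, base_channels = 1L, kernel_size = 3L)
  enc <- build_encoder(cfg, seed = 1L)
  expect_identical(n_params(enc), 9 + 1 + 2 + 18 + 2 + 36 + 2 + 4)
})

test_that("pyramid shapes halve spatially and grow in channels", {
  enc <- build_encoder(encoder_config(levels = 4L, base_channels = 8L), seed = 1L)
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  pyr <- extract_pyramid(enc, img)
  expect_identical(lapply(pyr, dim),
                   list(c(64L, 64L, 8L), c(32L, 32L, 16L),
                        c(16L, 16L, 32L), c(8L, 8L, 64L)))
  expect_identical(extract_pyramid(enc, img), pyr)  # determinism
})

test_that("odd-sized inputs are reflection-padded to divisibility", {
  enc <- build_encoder(encoder_config(levels = 3L, base_channels = 2L), seed = 2L)
  img <- matrix(runif(33 * 37), 33, 37)
  pyr <- extract_pyramid(enc, img)
  expect_identical(dim(pyr[[1]])[1:2], c(36L, 40L))
  padded <- pad_to_multiple(img, 4L)
  expect_identical(padded$image[1:33, 1:37], img)
})

test_that("a single-pixel change only perturbs level 1 inside its receptive field", {
  enc <- build_encoder(encoder_config(levels = 2L, base_channels = 4L), seed = 3L)
  set.seed(4)
  img <- matrix(runif(32 * 32), 32, 32)
  img2 <- img
  img2[16, 16] <- img2[16, 16] + 1
  p1 <- extract_pyramid(enc, img)[[1]]
  p2 <- extract_pyramid(enc, img2)[[1]]
  d <- abs(p1 - p2)
  # level 1 is a single 3x3 convolution (+ per-channel affine BN and GELU):
  # receptive field of pixel (16,16) is rows/cols 15..17
  inside <- d[15:17, 15:17, ]
  outside <- d
  outside[15:17, 15:17, ] <- 0
  expect_gt(max(inside), 0)
  expect_identical(max(outside), 0)
})

test_that("encoder is translation-covariant for shifts of the total stride", {
  enc <- build_encoder(encoder_config(levels = 3L, base_channels = 4L), seed = 5L)
  set.seed(6)
  big <- matrix(runif(80 * 80), 80, 80)
  s <- 4L  # total stride of a 3-level encoder
  a <- extract_pyramid(enc, big[1:64, 1:64])
  b <- extract_pyramid(enc, big[(1 + s):(64 + s), 1:64])
  # compare interiors at the coarsest level (16 x 16), margin 5 coarse
  # pixels so the crop clears every border-contaminated receptive field
  ia <- a[[3]][6:11, 6:11, ]
  ib <- b[[3]][5:10, 6:11, ]
  expect_equal(ia, ib, tolerance = 1e-10)
})
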