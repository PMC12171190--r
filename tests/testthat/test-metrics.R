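test_that("SSIM is 1 for identical images and q_spatial sums over inputs", {
  set.seed(51)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(q_spatial(x, list(x))$q_spatial, 1, tolerance = 1e-12)
  qs <- q_spatial(x, list(x, x))
  expect_equal(qs$q_spatial, 2, tolerance = 1e-12)
  expect_equal(qs$q_spatial_norm, 1, tolerance = 1e-12)
})

test_that("q_spatial drops when the fused image is noise-corrupted", {
  set.seed(52)
  inputs <- list(matrix(runif(32 * 32), 32, 32), matrix(runif(32 * 32), 32, 32))
  fused <- (inputs[[1]] + inputs[[2]]) / 2
  clean <- q_spatial(fused, inputs)$q_spatial
  noisy <- pmin(pmax(fused + matrix(rnorm(32 * 32, 0, 0.05), 32, 32), 0), 1)
  expect_lt(q_spatial(noisy, inputs)$q_spatial, clean)
})

test_that("entropy matches its closed forms", {
  expect_identical(q_info(matrix(0.42, 8, 8)), 0)
  # equal mass in all 256 bins
  vals <- rep((seq_len(256) - 0.5) / 256, each = 4)
  expect_equal(q_info(matrix(vals, 32, 32)), 8, tolerance = 1e-12)
  # two-value image with proportions 1/4, 3/4
  img <- matrix(c(rep(0.2, 16), rep(0.7, 48)), 8, 8)
  expect_equal(q_info(img), -(0.25 * log2(0.25) + 0.75 * log2(0.75)),
               tolerance = 1e-6)
  expect_equal(round(q_info(img), 4), 0.8113)
  expect_error(q_info(matrix(0.5, 4, 4), bins = 1L), "bins")
})

test_that("entropy is invariant to bin-preserving intensity permutations", {
  set.seed(53)
  levels <- (sample(256, 6) - 0.5) / 256
  img <- matrix(sample(levels, 400, replace = TRUE), 20, 20)
  perm <- (sample(256, 256) - 0.5) / 256
  remap <- matrix(perm[round(img * 256 + 0.5)], 20, 20)
  expect_equal(q_info(remap), q_info(img), tolerance = 1e-12)
})

test_that("q_edge vanishes on gradient-identical stacks and matches the oracle", {
  set.seed(54)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(q_edge(x, list(x)), 0)
  expect_identical(q_edge(x, list(x, x)), 0)
  for (i in 1:10) {
    f <- matrix(rnorm(16), 4, 4)
    a <- matrix(rnorm(16), 4, 4)
    b <- matrix(rnorm(16), 4, 4)
    expect_equal(q_edge(f, list(a, b)), oracle_q_edge(f, list(a, b)),
                 tolerance = 1e-6)
    expect_gte(q_edge(f, list(a)), 0)
  }
})

test_that("segmentation metrics match hand counts and conventions", {
  m <- matrix(0, 4, 4); m[1:2, 1:2] <- 1
  r <- seg_metrics(m, m)
  expect_equal(unname(r$metrics), rep(1, 4))
  # hand-counted 2x2 case: P = {(1,1),(1,2)}, T = {(1,2),(2,2)}
  p <- matrix(c(1, 0, 1, 0), 2, 2)
  t <- matrix(c(0, 0, 1, 1), 2, 2)
  r <- seg_metrics(p, t)
  expect_equal(r$metrics[["dice"]], 0.5)
  expect_equal(r$metrics[["iou"]], 1 / 3)
  expect_equal(r$metrics[["precision"]], 0.5)
  expect_equal(r$metrics[["recall"]], 0.5)
  # empty prediction vs nonempty truth
  r <- seg_metrics(matrix(0, 3, 3), matrix(1, 3, 3))
  expect_equal(unname(r$metrics), rep(0, 4))
  # both empty
  r <- seg_metrics(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(unname(r$metrics), rep(1, 4))
  expect_error(seg_metrics(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("Dice and IoU satisfy their algebraic identity on random masks", {
  set.seed(55)
  for (i in 1:200) {
    p <- rand_mask(6, 6, runif(1, 0.1, 0.9))
    t <- rand_mask(6, 6, runif(1, 0.1, 0.9))
    m <- seg_metrics(p, t)$metrics
    expect_equal(m[["dice"]], 2 * m[["iou"]] / (1 + m[["iou"]]),
                 tolerance = 1e-12)
  }
})

test_that("fusion_quality aggregates all metrics with invariant ranges", {
  set.seed(56)
  inputs <- list(matrix(runif(16 * 16), 16, 16), matrix(runif(16 * 16), 16, 16))
  fused <- laplacian_fuse(inputs, levels = 3L)
  fused <- pmin(pmax(fused, 0), 1)
  fq <- fusion_quality(fused, inputs)
  expect_true(fq$q_info >= 0 && fq$q_info <= 8)
  expect_gte(fq$q_edge, 0)
  expect_true(fq$q_spatial <= 2 + 1e-9)
})
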