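test_that("spatially constant maps give uniform attention", {
  f <- array(0.7, c(4, 5, 3))
  set.seed(1)
  w <- matrix(rnorm(9), 3, 3)
  a <- compute_attention(f, w)
  expect_equal(a, array(1 / 20, c(4, 5, 3)), tolerance = 1e-12)
  # zero weight matrix: uniform regardless of the input
  f2 <- array(rnorm(60), c(4, 5, 3))
  expect_equal(compute_attention(f2, matrix(0, 3, 3)),
               array(1 / 20, c(4, 5, 3)), tolerance = 1e-12)
})

test_that("attention matches the brute-force softmax oracle", {
  set.seed(2)
  f <- array(rnorm(4), c(2, 2, 1))
  expect_equal(compute_attention(f, diag(1)), oracle_attention(f, diag(1)),
               tolerance = 1e-6)
  for (i in 1:10) {
    f <- rand_map(3, 4, 2, seed = 10 + i)
    w <- matrix(rnorm(4), 2, 2)
    expect_equal(compute_attention(f, w), oracle_attention(f, w),
                 tolerance = 1e-6)
  }
})

test_that("attention maps are distributions and shift-invariant in the logits", {
  set.seed(3)
  for (i in 1:10) {
    f <- rand_map(5, 6, 3)
    w <- matrix(rnorm(9), 3, 3)
    a <- compute_attention(f, w)
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(apply(a, 3, sum), rep(1, 3), tolerance = 1e-5)
  }
  # adding a constant to every pixel adds a per-channel constant to the
  # logits; the attention is unchanged
  f <- rand_map(4, 4, 2, seed = 99)
  w <- matrix(rnorm(4), 2, 2)
  expect_equal(compute_attention(f + 3, w), compute_attention(f, w),
               tolerance = 1e-9)
})

test_that("attention is permutation-covariant in space", {
  f <- rand_map(4, 4, 2, seed = 5)
  w <- matrix(rnorm(4), 2, 2)
  a <- compute_attention(f, w)
  set.seed(6)
  pr <- sample(4); pc <- sample(4)
  fp <- f[pr, pc, , drop = FALSE]
  expect_equal(compute_attention(fp, w), a[pr, pc, , drop = FALSE],
               tolerance = 1e-12)
})

test_that("residual attention obeys its closed forms", {
  f <- rand_map(3, 3, 2, seed = 7)
  zero <- array(0, dim(f))
  one <- array(1, dim(f))
  expect_identical(apply_residual_attention(f, zero, residual = TRUE), f)
  expect_equal(apply_residual_attention(f, one, residual = TRUE), 2 * f)
  # plain mode equals the scalar elementwise-product loop
  a <- rand_map(3, 3, 2, seed = 8)
  expected <- array(0, dim(f))
  for (i in 1:3) for (j in 1:3) for (c in 1:2) {
    expected[i, j, c] <- a[i, j, c] * f[i, j, c]
  }
  expect_equal(apply_residual_attention(f, a, residual = FALSE), expected,
               tolerance = 1e-12)
})

test_that("residual mode never shrinks nonnegative features under nonnegative attention", {
  set.seed(9)
  f <- array(abs(rnorm(36)), c(3, 4, 3))
  a <- array(runif(36), c(3, 4, 3))
  out <- apply_residual_attention(f, a, residual = TRUE)
  expect_true(all(out >= f))
})

test_that("shape mismatches are contract errors", {
  expect_error(apply_residual_attention(rand_map(3, 3), rand_map(3, 4)),
               "mismatch")
  expect_error(compute_attention(rand_map(3, 3, 2), matrix(0, 3, 3)), "2 x 2")
})
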