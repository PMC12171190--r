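test_that("saliency matches its closed forms and the scalar-loop oracle", {
  expect_identical(saliency(array(0.3, c(5, 5, 2))), 0)
  # horizontal ramp with step d: mean abs gradient = d * (W-1)/W
  W <- 8; d <- 0.25
  ramp <- matrix(rep(seq(0, by = d, length.out = W), each = 6), 6, W)
  expect_equal(saliency(ramp), d * (W - 1) / W, tolerance = 1e-12)
  expect_equal(saliency(ramp), oracle_saliency(array(ramp, c(6, W, 1))),
               tolerance = 1e-12)
  for (i in 1:10) {
    f <- rand_map(4, 4, 2, seed = 20 + i)
    expect_equal(saliency(f), oracle_saliency(f), tolerance = 1e-6)
  }
})

test_that("saliency is exactly homogeneous of degree one", {
  f <- rand_map(6, 6, 3, seed = 31)
  for (c in c(2, 5.5, 100)) {
    expect_equal(saliency(c * f), c * saliency(f), tolerance = 1e-10)
  }
})

test_that("saliency weights follow the softmax closed forms", {
  for (n in c(2, 3, 7)) {
    expect_equal(saliency_weights(rep(1.3, n)), rep(1 / n, n))
  }
  expect_identical(saliency_weights(4.2), 1)
  d <- 0.8
  w <- saliency_weights(c(1 + d, 1))
  expect_equal(w, c(1 / (1 + exp(-d)), 1 / (1 + exp(d))), tolerance = 1e-12)
  expect_error(saliency_weights(numeric(0)), "empty")
})

test_that("saliency weights are permutation-equivariant and on the simplex", {
  set.seed(32)
  for (i in 1:20) {
    s <- rnorm(5)
    w <- saliency_weights(s)
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(sum(w), 1, tolerance = 1e-6)
    p <- sample(5)
    expect_equal(saliency_weights(s[p]), w[p], tolerance = 1e-12)
  }
})

test_that("global context is the elementwise mean", {
  m <- rand_map(4, 4, 2, seed = 33)
  expect_identical(global_context(list(m)), m)
  expect_equal(global_context(list(m, m, m)), m, tolerance = 1e-12)
  z <- array(0, dim(m)); o <- array(1, dim(m))
  expect_equal(global_context(list(z, o)), array(0.5, dim(m)))
  expect_error(global_context(list(m, rand_map(4, 5, 2))), "mismatch")
})

test_that("context attention has its zero-parameter closed form and bound", {
  f <- rand_map(5, 5, 3, seed = 34)
  g <- rand_map(5, 5, 3, seed = 35)
  expect_equal(context_attention(f, g), 0.5 * g, tolerance = 1e-12)
  expect_identical(context_attention(f, array(0, dim(f))), array(0, dim(f)))
  set.seed(36)
  for (i in 1:10) {
    f <- rand_map(4, 4, 2)
    g <- rand_map(4, 4, 2)
    params <- list(w = matrix(rnorm(4 * 2), 4, 2), b = rnorm(2))
    out <- context_attention(f, g, params)
    expect_true(all(abs(out) <= abs(g) + 1e-12))
  }
})

test_that("refine obeys its closed forms and the scalar oracle", {
  f <- rand_map(4, 4, 2, seed = 37)
  g <- rand_map(4, 4, 2, seed = 38)
  expect_identical(refine(f, g, alpha = 0), f)
  expect_equal(refine(f, f, alpha = 1), 2 * f)
  expected <- array(0, dim(f))
  for (i in 1:4) for (j in 1:4) for (c in 1:2) {
    expected[i, j, c] <- f[i, j, c] - 0.5 * g[i, j, c]
  }
  expect_equal(refine(f, g, alpha = -0.5), expected, tolerance = 1e-12)
})

test_that("fused output responds continuously to vanishing input noise", {
  # noise-stability contract: discrepancy of the full MFAFN+DFRS forward
  # pass shrinks to zero with the input noise level
  model <- mfafn_build(2L, encoder_config(levels = 3L, base_channels = 4L),
                       seed = 5L)
  cfg <- phantom_config(32, 32, 2, "blob", noise_sigma = 0, seed = 4L)
  ph <- generate_phantom(cfg)
  clean <- mfafn_predict(model, ph$images)
  disc <- sapply(c(0.05, 0.01, 0.001), function(s) {
    set.seed(77)
    noisy <- lapply(ph$images, function(im) {
      pmin(pmax(im + matrix(rnorm(length(im), 0, s), nrow(im)), 0), 1)
    })
    out <- mfafn_predict(model, noisy)
    mean(abs(out$fused - clean$fused))
  })
  expect_true(all(diff(disc) < 0))
  expect_gt(disc[1], disc[3])
})
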