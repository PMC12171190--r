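test_that("phantom generation is a pure function of its config", {
  cfg <- phantom_config(32, 32, 2, "branching", seed = 7L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a, b)
  cfg2 <- phantom_config(32, 32, 2, "branching", seed = 8L)
  expect_false(identical(generate_phantom(cfg2)$mask, a$mask))
})

test_that("identity offsets without complementary rendering give identical modalities", {
  cfg <- phantom_config(32, 32, 2, "blob", noise_sigma = 0,
                        modality_offsets = list(c(1, 0), c(1, 0)),
                        complementary = FALSE, seed = 3L)
  ph <- generate_phantom(cfg)
  expect_identical(ph$images[[1]], ph$images[[2]])
})

test_that("forced central ellipse mask area matches the analytic area within 2%", {
  for (seed in 1:3) {
    H <- 64L; W <- 64L
    a <- 14; b <- 9
    cfg <- phantom_config(H, W, 1, "blob", noise_sigma = 0,
                          blob_spec = list(c(W / 2, H / 2, a, b, 0.4)),
                          seed = seed)
    ph <- generate_phantom(cfg)
    analytic <- pi * a * b / (H * W)
    measured <- mean(ph$mask)
    expect_lt(abs(measured - analytic) / analytic, 0.02)
  }
})

test_that("generated images lie in [0,1] and masks are exactly binary", {
  for (structure in c("branching", "blob")) {
    cfg <- phantom_config(32, 32, 3, structure, noise_sigma = 0.2, seed = 11L)
    ph <- generate_phantom(cfg)
    for (im in ph$images) {
      expect_true(all(im >= 0 & im <= 1))
    }
    expect_true(all(ph$mask %in% c(0, 1)))
  }
})

test_that("phantom_config validates its invariants", {
  expect_error(phantom_config(height = 8), "height")
  expect_error(phantom_config(n_modalities = 0), "n_modalities")
  expect_error(phantom_config(contrast = 0), "contrast")
  expect_error(phantom_config(noise_sigma = -1), "noise_sigma")
})

test_that("degrade with kind none and zero-sigma noise are exact identities", {
  set.seed(5)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(degrade(x, degradation_spec("none")), x)
  expect_identical(degrade(x, degradation_spec("gaussian_noise", noise_sigma = 0)), x)
})

test_that("motion blur preserves constant images (unit-sum kernel)", {
  x <- matrix(0.42, 24, 24)
  out <- degrade(x, degradation_spec("motion_blur", blur_kernel = 5L, blur_sigma = 1))
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("JPEG round-trip error grows as quality drops", {
  ramp <- matrix(rep(seq(0, 1, length.out = 32), each = 32), 32, 32)
  set.seed(9)
  ramp <- pmin(pmax(ramp + matrix(rnorm(32 * 32, 0, 0.1), 32, 32), 0), 1)
  e30 <- mean(abs(jpeg_roundtrip(ramp, 30L) - ramp))
  e95 <- mean(abs(jpeg_roundtrip(ramp, 95L) - ramp))
  expect_gt(e30, e95)
})

test_that("degradation parameters are validated", {
  expect_error(degradation_spec("motion_blur", blur_kernel = 4L), "odd")
  expect_error(degradation_spec("jpeg", jpeg_quality = 0L), "1, 100")
  expect_error(degradation_spec("jpeg", jpeg_quality = 101L), "1, 100")
})

test_that("low-light degradation darkens and stays in range", {
  set.seed(2)
  x <- matrix(runif(32 * 32, 0.2, 1), 32, 32)
  out <- degrade(x, degradation_spec("low_light"))
  expect_true(all(out >= 0 & out <= 1))
  expect_true(all(out <= x + 1e-12))
})

test_that("noise degradation deviation is non-decreasing in sigma", {
  sigmas <- c(0.02, 0.05, 0.1, 0.2)
  devs <- sapply(sigmas, function(s) {
    spec <- degradation_spec("gaussian_noise", noise_sigma = s)
    mean(sapply(1:20, function(seed) {
      set.seed(seed)
      x <- matrix(runif(24 * 24, 0.2, 0.8), 24, 24)
      mean(abs(degrade(x, spec, seed = 100 + seed) - x))
    }))
  })
  expect_true(all(diff(devs) >= 0))
})

test_that("make_dataset writes a reproducible manifest with the right split", {
  cfg <- phantom_config(16, 16, 2, "blob", seed = 1L)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_dataset(8, 2, cfg, d1, seed = 1L)
  m2 <- make_dataset(8, 2, cfg, d2, seed = 1L)
  expect_length(m1$samples, 10L)
  splits <- vapply(m1$samples, function(s) s$split, character(1))
  expect_identical(sum(splits == "train"), 8L)
  expect_identical(sum(splits == "val"), 2L)
  # bit-identical files across re-runs
  f1 <- sort(list.files(d1, pattern = "png$"))
  expect_identical(f1, sort(list.files(d2, pattern = "png$")))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  ds <- load_dataset(file.path(d1, "manifest.json"))
  expect_length(ds$samples, 10L)
  expect_true(all(ds$samples[[1]]$mask %in% c(0, 1)))
})

test_that("an 80-20 dataset has train fraction 0.8", {
  cfg <- phantom_config(16, 16, 1, "blob", seed = 3L)
  d <- file.path(tempdir(), "ds80")
  unlink(d, recursive = TRUE)
  m <- make_dataset(80, 20, cfg, d, seed = 3L)
  splits <- vapply(m$samples, function(s) s$split, character(1))
  expect_equal(mean(splits == "train"), 0.8)
})

test_that("adding samples never perturbs earlier samples (counter-based seeds)", {
  cfg <- phantom_config(16, 16, 1, "blob", seed = 1L)
  da <- file.path(tempdir(), "dsa"); db <- file.path(tempdir(), "dsb")
  unlink(c(da, db), recursive = TRUE)
  make_dataset(2, 1, cfg, da, seed = 5L)
  make_dataset(4, 2, cfg, db, seed = 5L)
  for (f in list.files(da, pattern = "sample_000[12].*png$")) {
    expect_identical(readBin(file.path(da, f), "raw", 1e6),
                     readBin(file.path(db, f), "raw", 1e6))
  }
})
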