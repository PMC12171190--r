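test_that("the combined loss matches its closed forms", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  # near-perfect prediction drives the loss toward 0
  p <- ifelse(t == 1, 1 - 1e-9, 1e-9)
  expect_lt(seg_loss(p, t), 1e-6)
  # cross-entropy of probs = 0.5 is ln 2 per pixel (weights isolate the term)
  p5 <- matrix(0.5, 2, 2)
  expect_equal(seg_loss(p5, t, weights = c(0, 1)), log(2), tolerance = 1e-12)
  # soft-Dice closed form for constant probs p on mask fraction f
  pp <- 0.3; f <- 0.25
  tt <- matrix(0, 4, 4); tt[1:2, 1:2] <- 1   # fraction 0.25
  pmat <- matrix(pp, 4, 4)
  expect_equal(seg_loss(pmat, tt, weights = c(1, 0)),
               1 - 2 * pp * f / (pp + f), tolerance = 1e-12)
  expect_error(seg_loss(matrix(1.5, 2, 2), t), "\\[0,1\\]")
})

test_that("the learning-rate schedule matches its closed form at every epoch", {
  lr <- 1e-4; wu <- 5L; E <- 40L
  for (e in 1:E) {
    expected <- if (e <= wu) lr * e / wu else {
      lr * (1 + cos(pi * (e - wu) / (E - wu))) / 2
    }
    expect_equal(lr_schedule(e, lr, wu, E), expected, tolerance = 1e-15)
  }
  expect_equal(lr_schedule(wu, lr, wu, E), lr)   # ramp reaches lr
  expect_equal(lr_schedule(E, lr, wu, E), 0)     # anneals to zero
  expect_error(lr_schedule(1, lr, 10, 10), "warmup")
  expect_error(train_config(warmup = 40, max_epochs = 40), "warmup")
  expect_error(train_config(early_stop_patience = 0), "patience")
})

make_tiny_dataset <- function(n_train = 6L, n_val = 2L, seed = 1L) {
  cfg <- phantom_config(16, 16, 2, "blob", seed = seed)
  lapply(seq_len(n_train + n_val), function(s) {
    cfg$seed <- mfafuse:::derive_seed(seed, s)
    ph <- generate_phantom(cfg)
    list(id = s, split = if (s <= n_train) "train" else "val",
         images = ph$images, mask = ph$mask)
  })
}

test_that("training is reproducible under a fixed seed", {
  ds <- make_tiny_dataset()
  enc <- encoder_config(levels = 2L, base_channels = 2L)
  cfg <- train_config(warmup = 1L, max_epochs = 3L, batch_size = 4L, seed = 5L)
  f1 <- train(mfafn_build(2L, enc, seed = 3L), ds, cfg)
  f2 <- train(mfafn_build(2L, enc, seed = 3L), ds, cfg)
  expect_identical(f1$history, f2$history)
})

test_that("early stopping halts after `patience` non-improving epochs", {
  ds <- make_tiny_dataset()
  enc <- encoder_config(levels = 2L, base_channels = 2L)
  # an unreachable threshold forces empty predictions, so validation Dice
  # is 0 at every epoch and never improves after epoch 1
  cfg <- train_config(max_epochs = 20L, early_stop_patience = 1L,
                      batch_size = 4L, threshold = 2, seed = 5L)
  fit <- train(mfafn_build(2L, enc, seed = 3L), ds, cfg)
  expect_true(fit$stopped_early)
  expect_identical(nrow(fit$history), 2L)
  expect_identical(fit$best_epoch, 1L)
})

test_that("postprocess removes small components after closing", {
  m <- matrix(0, 8, 8)
  m[2, 2] <- 1; m[2, 3] <- 1                   # 2-pixel island
  expect_identical(postprocess(m, min_size = 5L), matrix(0, 8, 8))
  # a solid block with no gaps and no small components is a fixed point
  m2 <- matrix(0, 8, 8); m2[3:6, 3:6] <- 1
  expect_identical(postprocess(m2, min_size = 5L), m2)
})

test_that("postprocess keeps exactly the components above min_size", {
  # 8x8 mask with components of sizes 2, 6 and 9 (well separated so the
  # 3x3 closing cannot merge or alter them)
  m <- matrix(0, 10, 14)
  m[2:3, 2] <- 1                               # size 2
  m[6:8, 4:5] <- 1                             # size 6
  m[2:4, 9:11] <- 1                            # size 9
  out <- postprocess(m, min_size = 5L)
  lab <- label_components(out)
  expect_identical(max(lab), 2L)
  expect_identical(sum(out), 15)
})

test_that("label_components uses 8-connectivity", {
  m <- matrix(0, 4, 4)
  m[1, 1] <- 1; m[2, 2] <- 1                   # diagonal neighbors: one component
  m[4, 4] <- 1                                 # isolated
  lab <- label_components(m)
  expect_identical(max(lab), 2L)
  expect_identical(lab[1, 1], lab[2, 2])
  expect_false(lab[4, 4] == lab[1, 1])
})

test_that("ablation variants enforce their structural contracts", {
  enc <- encoder_config(levels = 3L, base_channels = 4L)
  full <- build_variant("full", 2L, enc, seed = 6L)
  noms <- build_variant("no_multiscale", 2L, enc, seed = 6L)
  noat <- build_variant("no_attention", 2L, enc, seed = 6L)
  nocr <- build_variant("no_context_refine", 2L, enc, seed = 6L)
  expect_identical(noms$config$encoder$levels, 1L)
  # widened channels keep the budget within 25% of the full model
  expect_lt(abs(n_params(noms) - n_params(full)) / n_params(full), 0.25)
  expect_identical(noat$config$attention, "bypass")
  expect_false(nocr$config$context_refinement)
  # alpha frozen: not among trainable parameters
  expect_false(any(grepl("^alpha", names(mfafuse:::trainable_params(nocr)))))
  # at initialization, full and no_context_refine coincide exactly
  cfgp <- phantom_config(16, 16, 2, "blob", seed = 8L)
  ph <- generate_phantom(cfgp)
  expect_identical(mfafn_predict(full, ph$images)$seg_probs,
                   mfafn_predict(nocr, ph$images)$seg_probs)
})

test_that("cross-validation assigns every sample to exactly one validation fold", {
  ds <- make_tiny_dataset(6L, 2L)
  enc <- encoder_config(levels = 2L, base_channels = 2L)
  cfg <- train_config(warmup = 1L, max_epochs = 2L, batch_size = 4L, seed = 9L)
  cv <- cross_validate(ds, k = 2L, encoder = enc, config = cfg)
  expect_length(cv$folds, 2L)
  expect_identical(cv$summary$metric, c("dice", "iou", "precision", "recall"))
  expect_true(all(is.finite(cv$summary$mean)))
  expect_error(cross_validate(ds, k = 1L), "k must be")
})

test_that("run_robustness reports one clean row plus one row per condition", {
  ds <- make_tiny_dataset()
  model <- mfafn_build(2L, encoder_config(levels = 2L, base_channels = 2L),
                       seed = 4L)
  tab <- run_robustness(model, ds, threshold = 0.5, seed = 1L)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$condition[1], "clean")
  expect_true(all(c("low_light", "jpeg", "motion_blur", "gaussian_noise")
                  %in% tab$condition))
  # kind = none equals the standard evaluation exactly
  tab2 <- run_robustness(model, ds,
                         conditions = list(none = degradation_spec("none")),
                         threshold = 0.5, seed = 1L)
  expect_identical(tab2[tab2$condition == "none", -1],
                   structure(tab2[tab2$condition == "clean", -1],
                             row.names = 2L))
})
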