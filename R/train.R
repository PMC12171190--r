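# Tiny-scale CPU training harness: Dice + cross-entropy loss, Adam with a
# linear warm-up followed by cosine annealing, early stopping on validation
# Dice, morphological post-processing, and the ablation / robustness
# benchmark drivers.

#' Combined Dice and cross-entropy segmentation loss
#'
#' `w_dice * (1 - softDice) + w_ce * BCE`. Soft Dice is
#' `2 * sum(p*t) / (sum(p) + sum(t))` (1 for empty/empty); binary
#' cross-entropy is averaged over pixels with probabilities clamped away from
#' \{0,1\} inside the logarithms only.
#'
#' @param pred_probs prediction probabilities in \[0,1\], any array shape.
#' @param truth_mask binary mask of identical shape.
#' @param weights `c(w_dice, w_ce)`.
#' @return scalar loss.
#' @export
seg_loss <- function(pred_probs, truth_mask, weights = c(0.5, 0.5)) {
  if (!identical(dim(pred_probs), dim(truth_mask))) {
    stop("seg_loss: shape mismatch", call. = FALSE)
  }
  if (any(pred_probs < -1e-8) || any(pred_probs > 1 + 1e-8)) {
    stop("seg_loss: probabilities outside [0,1]", call. = FALSE)
  }
  p <- as.vector(pred_probs); t <- as.vector(truth_mask)
  S <- sum(p) + sum(t)
  dice <- if (S > 0) 2 * sum(p * t) / S else 1
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  bce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
  weights[1L] * (1 - dice) + weights[2L] * bce
}

#' Learning-rate schedule: linear warm-up then cosine annealing
#'
#' Epochs 1..warmup ramp linearly from `lr/warmup` to `lr`; thereafter the
#' rate follows `lr * (1 + cos(pi * (e - w) / (E - w))) / 2`, reaching 0 at
#' the final epoch.
#'
#' @param epoch current epoch (1-based).
#' @param lr base learning rate.
#' @param warmup warm-up epochs.
#' @param max_epochs total epoch budget E.
#' @return the learning rate for `epoch`.
#' @export
lr_schedule <- function(epoch, lr = 1e-4, warmup = 5L, max_epochs = 100L) {
  if (warmup >= max_epochs) stop("lr_schedule: warmup must be < max_epochs", call. = FALSE)
  if (epoch <= warmup) {
    lr * epoch / warmup
  } else {
    lr * (1 + cos(pi * (epoch - warmup) / (max_epochs - warmup))) / 2
  }
}

#' Training configuration
#'
#' Defaults follow the reference recipe (Adam at 1e-4, cosine annealing with
#' a 5-epoch warm-up, early stopping on validation Dice with patience 10,
#' equal Dice/cross-entropy loss weights); `max_epochs` and `batch_size`
#' default to the tiny CPU scale of the phantom benchmark.
#'
#' @param lr initial learning rate.
#' @param warmup warm-up epochs (must be < `max_epochs`).
#' @param early_stop_patience epochs without validation-Dice improvement
#'   before stopping (>= 1).
#' @param batch_size mini-batch size.
#' @param max_epochs epoch budget.
#' @param loss_weights `c(w_dice, w_ce)`.
#' @param threshold probability threshold for mask prediction.
#' @param seed integer seed (shuffling).
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, warmup = 5L, early_stop_patience = 10L,
                         batch_size = 8L, max_epochs = 40L,
                         loss_weights = c(0.5, 0.5), threshold = 0.5,
                         seed = 1L) {
  warmup <- as.integer(warmup); max_epochs <- as.integer(max_epochs)
  early_stop_patience <- as.integer(early_stop_patience)
  if (warmup >= max_epochs) stop("train_config: warmup must be < max_epochs", call. = FALSE)
  if (early_stop_patience < 1L) stop("train_config: patience must be >= 1", call. = FALSE)
  structure(list(lr = lr, warmup = warmup,
                 early_stop_patience = early_stop_patience,
                 batch_size = as.integer(batch_size), max_epochs = max_epochs,
                 loss_weights = loss_weights, threshold = threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

# stack a list of samples into per-modality (H, W, B) arrays plus masks
stack_samples <- function(samples) {
  n_mod <- length(samples[[1L]]$images)
  H <- nrow(samples[[1L]]$mask); W <- ncol(samples[[1L]]$mask)
  B <- length(samples)
  imgs <- lapply(seq_len(n_mod), function(i) {
    a <- array(0, c(H, W, B))
    for (b in seq_len(B)) a[, , b] <- samples[[b]]$images[[i]]
    a
  })
  masks <- array(0, c(H, W, 1L, B))
  for (b in seq_len(B)) masks[, , 1L, b] <- samples[[b]]$mask
  list(images = imgs, masks = masks, B = B)
}

# mean validation Dice of thresholded predictions (chunked to bound memory)
eval_dice <- function(model, samples, threshold = 0.5, chunk = 16L) {
  mean(unlist(lapply(seq(1L, length(samples), by = chunk), function(start) {
    sub <- samples[start:min(start + chunk - 1L, length(samples))]
    st <- stack_samples(sub)
    out <- mfafn_forward(model, st$images, tape = NULL, training = FALSE)
    pv <- out$seg$value
    vapply(seq_len(st$B), function(b) {
      pred <- (pv[, , 1L, b] >= threshold) * 1
      seg_metrics(pred, st$masks[, , 1L, b])$metrics[["dice"]]
    }, numeric(1))
  })))
}

#' Train an MFAFN+DFRS model on a phantom dataset
#'
#' Mini-batch Adam with the warm-up + cosine schedule, per-epoch validation
#' Dice, early stopping, and best-checkpoint tracking. Fully seeded: the same
#' seed, model and data reproduce the loss history exactly.
#'
#' @param model an [mfafn_build()] model (modified in place; the best
#'   parameters are restored before returning).
#' @param dataset a list with `samples` as returned by [load_dataset()], or a
#'   plain list of samples (`images`, `mask`, `split`).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `history` (data.frame: epoch, lr, train_loss, val_dice),
#'   `best_epoch`, `best_val_dice`, `stopped_early`, and `model`.
#' @export
train <- function(model, dataset, config = train_config(), verbose = FALSE) {
  samples <- if (!is.null(dataset$samples)) dataset$samples else dataset
  splits <- vapply(samples, function(s) s$split, character(1))
  tr <- samples[splits == "train"]
  va <- samples[splits == "val"]
  if (length(tr) == 0L || length(va) == 0L) {
    stop("train: need non-empty train and val splits", call. = FALSE)
  }
  params <- trainable_params(model)
  opt <- adam_new(params)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(config$seed, 77L))
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_dice = numeric())
  best_dice <- -Inf
  best_epoch <- 0L
  best_values <- NULL
  bad_epochs <- 0L
  stopped_early <- FALSE
  for (epoch in seq_len(config$max_epochs)) {
    lr_e <- lr_schedule(epoch, config$lr, config$warmup, config$max_epochs)
    ord <- sample(length(tr))
    losses <- numeric(0)
    for (start in seq(1L, length(tr), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(tr))]
      st <- stack_samples(tr[idx])
      tape <- ad_tape()
      out <- mfafn_forward(model, st$images, tape = tape, training = TRUE)
      loss <- nd_seg_loss(tape, out$seg, st$masks,
                          w_dice = config$loss_weights[1L],
                          w_ce = config$loss_weights[2L])
      if (!is.finite(loss$value)) {
        stop(sprintf("train: non-finite loss at epoch %d (diverged)", epoch),
             call. = FALSE)
      }
      ad_backward(tape, loss)
      adam_step(opt, lr_e)
      losses <- c(losses, loss$value)
    }
    vd <- eval_dice(model, va, config$threshold)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr_e,
                                         train_loss = mean(losses),
                                         val_dice = vd))
    if (verbose) {
      message(sprintf("epoch %3d lr %.2e loss %.4f val Dice %.4f",
                      epoch, lr_e, mean(losses), vd))
    }
    if (vd > best_dice) {
      best_dice <- vd
      best_epoch <- epoch
      best_values <- lapply(model$params, function(p) p$value)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$early_stop_patience) {
        stopped_early <- TRUE
        break
      }
    }
  }
  if (!is.null(best_values)) {
    for (nm in names(best_values)) model$params[[nm]]$value <- best_values[[nm]]
  }
  list(history = history, best_epoch = best_epoch, best_val_dice = best_dice,
       stopped_early = stopped_early, model = model)
}

#' K-fold cross-validation over a phantom dataset
#'
#' Partitions the samples into k folds (seeded), trains a fresh model per
#' fold with the remaining folds as the training split, and reports
#' per-fold and aggregate validation metrics. Off by default in the
#' benchmarks: at phantom scale the single held-out split covers the same
#' machinery at a fifth of the cost.
#'
#' @param samples list of samples (`images`, `mask`; any `split` labels are
#'   ignored and reassigned per fold).
#' @param k number of folds (default 5).
#' @param encoder an [encoder_config()] for the per-fold models.
#' @param config a [train_config()]; its seed also drives the fold
#'   assignment and per-fold model initialization.
#' @param n_modalities number of input modalities.
#' @return list with `folds` (per-fold fit + metrics) and `summary`
#'   (mean and sd of the four overlap metrics across folds).
#' @export
cross_validate <- function(samples, k = 5L, encoder = encoder_config(),
                           config = train_config(), n_modalities = 2L) {
  k <- as.integer(k)
  if (k < 2L || k > length(samples)) {
    stop("cross_validate: k must be in [2, n_samples]", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(config$seed, 55L))
  fold_id <- sample(rep(seq_len(k), length.out = length(samples)))
  folds <- lapply(seq_len(k), function(f) {
    ds <- lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      s$split <- if (fold_id[i] == f) "val" else "train"
      s
    })
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100L + f)
    model <- mfafn_build(n_modalities, encoder, seed = cfg$seed)
    fit <- train(model, ds, cfg)
    va <- ds[vapply(ds, function(s) s$split, character(1)) == "val"]
    list(fold = f, best_epoch = fit$best_epoch,
         metrics = eval_seg_metrics(fit$model, va, config$threshold))
  })
  m <- do.call(rbind, lapply(folds, function(f) f$metrics))
  list(folds = folds,
       summary = data.frame(metric = colnames(m),
                            mean = colMeans(m),
                            sd = apply(m, 2L, stats::sd),
                            row.names = NULL))
}

# ---- morphological post-processing ------------------------------------------

# 3x3 neighborhood max/min with a chosen out-of-image value
.neigh_op <- function(mask, op, pad_val) {
  H <- nrow(mask); W <- ncol(mask)
  xp <- matrix(pad_val, H + 2L, W + 2L)
  xp[1L + seq_len(H), 1L + seq_len(W)] <- mask
  out <- matrix(pad_val, H, W)
  first <- TRUE
  for (a in 0:2) for (b in 0:2) {
    sl <- xp[a + seq_len(H), b + seq_len(W)]
    out <- if (first) sl else op(out, sl)
    first <- FALSE
  }
  out
}

#' Label connected components (8-connectivity)
#'
#' @param mask binary matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  lab <- matrix(seq_along(mask), nrow(mask), ncol(mask)) * (mask == 1)
  H <- nrow(mask); W <- ncol(mask)
  repeat {
    xp <- matrix(0L, H + 2L, W + 2L)
    xp[1L + seq_len(H), 1L + seq_len(W)] <- lab
    nb <- lab
    for (a in 0:2) for (b in 0:2) {
      sl <- xp[a + seq_len(H), b + seq_len(W)]
      nb <- ifelse(nb > 0 & sl > 0, pmin(nb, sl), nb)
    }
    if (identical(nb, lab)) break
    lab <- nb
  }
  # renumber labels consecutively
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab <- matrix(match(lab, c(0, u)) - 1L, H, W)
  lab
}

#' Morphological post-processing of a segmentation mask
#'
#' 3 x 3 morphological closing (dilation then erosion) followed by removal of
#' 8-connected components smaller than `min_size` pixels.
#'
#' @param mask binary H x W matrix.
#' @param min_size minimum surviving component size in pixels.
#' @return cleaned binary mask.
#' @export
postprocess <- function(mask, min_size = 5L) {
  stopifnot(all(mask %in% c(0, 1)))
  dilated <- .neigh_op(mask, pmax, 0)
  closed <- .neigh_op(dilated, pmin, 0)   # background padding, as in scipy
  lab <- label_components(closed)
  if (max(lab) == 0L) return(closed * 0)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  (matrix(lab %in% keep, nrow(mask), ncol(mask))) * 1
}

# ---- ablation and robustness benchmarks -------------------------------------

# choose a widened single-scale base channel count whose parameter budget is
# closest to the full model's
.widened_base <- function(target_params, n_modalities, encoder_cfg) {
  best <- encoder_cfg$base_channels
  best_gap <- Inf
  for (base in seq(encoder_cfg$base_channels, 16L * encoder_cfg$base_channels)) {
    cfg1 <- encoder_config(levels = 1L, base_channels = base,
                           kernel_size = encoder_cfg$kernel_size,
                           channel_growth = encoder_cfg$channel_growth,
                           in_channels = encoder_cfg$in_channels)
    m <- mfafn_build(n_modalities, cfg1, seed = 1L)
    gap <- abs(n_params(m) - target_params)
    if (gap < best_gap) {
      best_gap <- gap
      best <- base
    }
    if (n_params(m) > target_params) break
  }
  best
}

#' Build an ablation variant of the MFAFN+DFRS model
#'
#' Variants: `"full"`; `"no_multiscale"` (single-scale encoder, channels
#' widened to match the full parameter budget); `"no_attention"` (alignment
#' bypass, F-hat = F); `"no_context_refine"` (per-scale alpha frozen at 0, so
#' at initialization its forward pass is bit-identical to the full model's).
#'
#' @param variant one of the four variant names.
#' @param n_modalities number of input modalities.
#' @param encoder base [encoder_config()] of the full model.
#' @param seed parameter initialization seed.
#' @return an `mfafn_model`.
#' @export
build_variant <- function(variant = c("full", "no_multiscale", "no_attention",
                                      "no_context_refine"),
                          n_modalities = 2L, encoder = encoder_config(),
                          seed = 1L) {
  variant <- match.arg(variant)
  switch(variant,
    full = mfafn_build(n_modalities, encoder, seed = seed),
    no_attention = mfafn_build(n_modalities, encoder, attention = "bypass",
                               seed = seed),
    no_context_refine = mfafn_build(n_modalities, encoder,
                                    context_refinement = FALSE, seed = seed),
    no_multiscale = {
      full <- mfafn_build(n_modalities, encoder, seed = seed)
      base <- .widened_base(n_params(full), n_modalities, encoder)
      cfg1 <- encoder_config(levels = 1L, base_channels = base,
                             kernel_size = encoder$kernel_size,
                             channel_growth = encoder$channel_growth,
                             in_channels = encoder$in_channels)
      mfafn_build(n_modalities, cfg1, seed = seed)
    })
}

#' Run the ablation benchmark
#'
#' Trains each variant on identical phantom data for each seed and reports
#' mean and standard deviation (over seeds) of validation Dice, IoU,
#' Precision and Recall, plus an ordering summary against the full model.
#'
#' @param dataset dataset (as for [train()]).
#' @param variants character vector of variant names.
#' @param seeds integer vector of >= 2 seeds.
#' @param encoder base [encoder_config()].
#' @param config a [train_config()] (its seed is replaced per run).
#' @param verbose print progress.
#' @return list with `table` (one row per variant) and `runs` (per-run
#'   results, including failures flagged in `failed`).
#' @export
run_ablation <- function(dataset, variants = c("full", "no_multiscale",
                                               "no_attention",
                                               "no_context_refine"),
                         seeds = c(1L, 2L, 3L), encoder = encoder_config(),
                         config = train_config(), verbose = FALSE) {
  if (length(seeds) < 2L) stop("run_ablation: need >= 2 seeds", call. = FALSE)
  samples <- if (!is.null(dataset$samples)) dataset$samples else dataset
  n_mod <- length(samples[[1L]]$images)
  va <- samples[vapply(samples, function(s) s$split, character(1)) == "val"]
  runs <- list()
  for (variant in variants) {
    for (seed in seeds) {
      res <- tryCatch({
        model <- build_variant(variant, n_mod, encoder, seed = seed)
        cfg <- config
        cfg$seed <- as.integer(seed)
        fit <- train(model, dataset, cfg, verbose = FALSE)
        mets <- eval_seg_metrics(fit$model, va, config$threshold)
        list(variant = variant, seed = seed, failed = FALSE,
             best_epoch = fit$best_epoch, metrics = mets)
      }, error = function(e) {
        list(variant = variant, seed = seed, failed = TRUE,
             error = conditionMessage(e), metrics = NULL)
      })
      if (verbose) {
        message(sprintf("ablation %-18s seed %d: %s", variant, seed,
                        if (res$failed) paste("FAILED:", res$error)
                        else sprintf("Dice %.4f", res$metrics[["dice"]])))
      }
      runs[[length(runs) + 1L]] <- res
    }
  }
  tab <- do.call(rbind, lapply(variants, function(v) {
    ok <- Filter(function(r) r$variant == v && !r$failed, runs)
    if (length(ok) == 0L) {
      return(data.frame(variant = v, n_ok = 0L, dice_mean = NA, dice_sd = NA,
                        iou_mean = NA, precision_mean = NA, recall_mean = NA))
    }
    m <- do.call(rbind, lapply(ok, function(r) r$metrics))
    data.frame(variant = v, n_ok = length(ok),
               dice_mean = mean(m[, "dice"]), dice_sd = stats::sd(m[, "dice"]),
               iou_mean = mean(m[, "iou"]),
               precision_mean = mean(m[, "precision"]),
               recall_mean = mean(m[, "recall"]))
  }))
  full_dice <- tab$dice_mean[tab$variant == "full"]
  tab$dice_vs_full <- tab$dice_mean - if (length(full_dice)) full_dice else NA
  list(table = tab, runs = runs)
}

# mean segmentation metrics of a model over samples (chunked to bound memory)
eval_seg_metrics <- function(model, samples, threshold = 0.5, chunk = 16L) {
  m <- do.call(rbind, lapply(seq(1L, length(samples), by = chunk), function(start) {
    sub <- samples[start:min(start + chunk - 1L, length(samples))]
    st <- stack_samples(sub)
    out <- mfafn_forward(model, st$images, tape = NULL, training = FALSE)
    pv <- out$seg$value
    do.call(rbind, lapply(seq_len(st$B), function(b) {
      pred <- (pv[, , 1L, b] >= threshold) * 1
      seg_metrics(pred, st$masks[, , 1L, b])$metrics
    }))
  }))
  colMeans(m)
}

#' Run the robustness benchmark on a trained model
#'
#' Evaluates validation Dice/IoU/Precision/Recall on clean inputs and under
#' each degradation condition applied to every modality image.
#'
#' @param model a trained `mfafn_model`.
#' @param dataset dataset (as for [train()]).
#' @param conditions named list of [degradation_spec()]s; defaults to
#'   [standard_conditions()].
#' @param threshold mask probability threshold.
#' @param seed seed for stochastic degradations.
#' @return data.frame with one `clean` row plus one row per condition.
#' @export
run_robustness <- function(model, dataset, conditions = standard_conditions(),
                           threshold = 0.5, seed = 1L) {
  samples <- if (!is.null(dataset$samples)) dataset$samples else dataset
  va <- samples[vapply(samples, function(s) s$split, character(1)) == "val"]
  rows <- list()
  mets <- eval_seg_metrics(model, va, threshold)
  rows[["clean"]] <- data.frame(condition = "clean", t(mets))
  for (nm in names(conditions)) {
    spec <- conditions[[nm]]
    deg <- lapply(seq_along(va), function(k) {
      s <- va[[k]]
      s$images <- lapply(seq_along(s$images), function(i) {
        degrade(s$images[[i]], spec, seed = derive_seed(seed, k * 131L + i))
      })
      s
    })
    mets <- eval_seg_metrics(model, deg, threshold)
    rows[[nm]] <- data.frame(condition = nm, t(mets))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
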