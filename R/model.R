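# Full MFAFN + DFRS network: shared multi-scale encoder applied to each
# input image, per-scale attention alignment, adaptive weighted fusion
# (saliency-softmax or learned-softmax weights), context-aware refinement,
# and a U-Net-style transposed-convolution decoder with fused-image and
# segmentation heads.

#' Build the MFAFN+DFRS model
#'
#' @param n_modalities number of registered input images N.
#' @param encoder an [encoder_config()].
#' @param attention `"residual"` (F + A*F, the default), `"plain"` (A*F) or
#'   `"bypass"` (F, the "without attention" ablation).
#' @param weight_mode `"saliency"` (gradient-saliency softmax weights,
#'   treated as constants during backpropagation) or `"learned"`
#'   (free per-scale parameters passed through a softmax).
#' @param context_refinement enable the alpha-gated global-context refinement;
#'   when `FALSE` the per-scale alpha is frozen at 0, making the refinement
#'   path the identity.
#' @param seed integer seed for parameter initialization.
#' @return object of class `mfafn_model`.
#' @export
mfafn_build <- function(n_modalities = 2L, encoder = encoder_config(),
                        attention = c("residual", "plain", "bypass"),
                        weight_mode = c("saliency", "learned"),
                        context_refinement = TRUE, seed = 1L) {
  attention <- match.arg(attention)
  weight_mode <- match.arg(weight_mode)
  enc <- build_encoder(encoder, seed = seed)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(seed, 202L))
  L <- encoder$levels
  ch <- encoder$channels
  params <- enc$params
  states <- enc$states
  for (l in seq_len(L)) {
    # bias-free 1x1 channel-mixing attention transform, one per scale
    params[[paste0("att", l, "_w")]] <-
      ad_param(array(stats::rnorm(ch[l]^2, 0, 1 / sqrt(ch[l])), c(1L, 1L, ch[l], ch[l])))
    # context gate: zero-init -> gate is exactly 0.5 at start
    params[[paste0("gate", l, "_w")]] <- ad_param(array(0, c(1L, 1L, 2L * ch[l], ch[l])))
    params[[paste0("gate", l, "_b")]] <- ad_param(numeric(ch[l]))
    # refinement gain, zero-init -> refinement starts as the identity
    params[[paste0("alpha", l)]] <- ad_param(0)
  }
  if (weight_mode == "learned") {
    params$fuse_theta <- ad_param(matrix(0, n_modalities, L))
  }
  if (L > 1L) {
    for (l in seq_len(L - 1L)) {
      params[[paste0("up", l, "_w")]] <-
        ad_param(he_init(c(2L, 2L, ch[l + 1L], ch[l]), 4L * ch[l + 1L]))
      params[[paste0("up", l, "_b")]] <- ad_param(numeric(ch[l]))
      params[[paste0("dconv", l, "_w")]] <-
        ad_param(he_init(c(3L, 3L, 2L * ch[l], ch[l]), 9L * 2L * ch[l]))
      params[[paste0("dconv", l, "_b")]] <- ad_param(numeric(ch[l]))
      params[[paste0("dbn", l, "_gamma")]] <- ad_param(rep(1, ch[l]))
      params[[paste0("dbn", l, "_beta")]] <- ad_param(numeric(ch[l]))
      states[[paste0("dbn", l)]] <- bn_state(ch[l])
    }
  } else {
    params$dconv1_w <- ad_param(he_init(c(3L, 3L, ch[1L], ch[1L]), 9L * ch[1L]))
    params$dconv1_b <- ad_param(numeric(ch[1L]))
    params$dbn1_gamma <- ad_param(rep(1, ch[1L]))
    params$dbn1_beta <- ad_param(numeric(ch[1L]))
    states$dbn1 <- bn_state(ch[1L])
  }
  params$head_seg_w <- ad_param(he_init(c(1L, 1L, ch[1L], 1L), ch[1L]))
  params$head_seg_b <- ad_param(numeric(1))
  params$head_fus_w <- ad_param(he_init(c(1L, 1L, ch[1L], 1L), ch[1L]))
  params$head_fus_b <- ad_param(numeric(1))
  model <- list(config = list(n_modalities = as.integer(n_modalities),
                              encoder = encoder, attention = attention,
                              weight_mode = weight_mode,
                              context_refinement = isTRUE(context_refinement),
                              seed = as.integer(seed)),
                params = params, states = states)
  model$encoder <- structure(list(config = encoder, params = params,
                                  states = states, seed = seed),
                             class = "mfafn_encoder")
  class(model) <- "mfafn_model"
  model
}

# parameters updated by the optimizer (alpha excluded when refinement is off)
trainable_params <- function(model) {
  p <- model$params
  if (!model$config$context_refinement) {
    p <- p[!grepl("^alpha", names(p))]
  }
  p
}

# forward pass; images: list of N arrays (H, W, B) or matrices (B = 1).
# All N modalities are pushed through the shared encoder and attention in a
# single modality-batched tensor (slice (i-1)*B + b = modality i, sample b),
# which also makes batch-normalization statistics modality-pooled. Returns
# nodes for segmentation probabilities and fused image plus the fusion
# weights actually used (L x N matrix; batch-averaged for saliency mode).
mfafn_forward <- function(model, images, tape = NULL, training = FALSE) {
  cfg <- model$config
  L <- cfg$encoder$levels
  N <- length(images)
  stopifnot(N == cfg$n_modalities)
  p <- model$params
  images <- lapply(images, function(im) {
    if (is.matrix(im)) im <- array(im, c(dim(im), 1L))
    stopifnot(length(dim(im)) == 3L)
    im
  })
  H <- dim(images[[1L]])[1L]; W <- dim(images[[1L]])[2L]
  B <- dim(images[[1L]])[3L]
  xall <- array(0, c(H, W, 1L, N * B))
  for (i in seq_len(N)) xall[, , 1L, (i - 1L) * B + seq_len(B)] <- images[[i]]
  x <- ad_const(xall)
  pyr <- encoder_forward(model$encoder, x, tape = tape, training = training)
  # per-scale attention alignment, fusion weights, fusion + refinement
  weights_used <- matrix(0, L, N)
  refined <- vector("list", L)
  for (l in seq_len(L)) {
    f <- pyr[[l]]
    aligned <- if (cfg$attention == "bypass") {
      f
    } else {
      nd_attention(tape, f, p[[paste0("att", l, "_w")]],
                   residual = cfg$attention == "residual")
    }
    w <- if (cfg$weight_mode == "saliency") {
      s <- matrix(saliency_per_slice(aligned$value), B, N)   # col i = modality i
      matrix(apply(s, 1L, saliency_weights), N, B)           # N x B simplex cols
    } else {
      nd_softmax_vec(tape, theta_col(tape, p$fuse_theta, l))
    }
    weights_used[l, ] <- if (ad_is_node(w)) as.numeric(w$value) else rowMeans(w)
    fused <- nd_group_wsum(tape, aligned, w, N, B)
    if (cfg$context_refinement) {
      glob <- nd_group_wsum(tape, aligned, matrix(1 / N, N, B), N, B)
      refined[[l]] <- nd_gate_refine(tape, fused, glob,
                                     p[[paste0("gate", l, "_w")]],
                                     p[[paste0("gate", l, "_b")]],
                                     p[[paste0("alpha", l)]])
    } else {
      refined[[l]] <- fused
    }
  }
  # decoder: coarse to fine with same-scale skip injection
  if (L > 1L) {
    h <- refined[[L]]
    for (l in seq(L - 1L, 1L)) {
      h <- nd_convt2d(tape, h, p[[paste0("up", l, "_w")]], p[[paste0("up", l, "_b")]])
      h <- nd_concat_c(tape, h, refined[[l]])
      h <- nd_conv2d(tape, h, p[[paste0("dconv", l, "_w")]],
                     p[[paste0("dconv", l, "_b")]], stride = 1L, pad = 1L)
      h <- nd_bn_gelu(tape, h, p[[paste0("dbn", l, "_gamma")]],
                      p[[paste0("dbn", l, "_beta")]],
                      model$states[[paste0("dbn", l)]], training = training)
    }
  } else {
    h <- nd_conv2d(tape, refined[[1L]], p$dconv1_w, p$dconv1_b, stride = 1L, pad = 1L)
    h <- nd_bn_gelu(tape, h, p$dbn1_gamma, p$dbn1_beta, model$states$dbn1,
                    training = training)
  }
  seg_logits <- nd_conv2d(tape, h, p$head_seg_w, p$head_seg_b, stride = 1L, pad = 0L)
  seg <- nd_sigmoid(tape, seg_logits)
  fus_logits <- nd_conv2d(tape, h, p$head_fus_w, p$head_fus_b, stride = 1L, pad = 0L)
  fused_img <- nd_sigmoid(tape, fus_logits)
  list(seg = seg, fused = fused_img, weights = weights_used)
}

# extract the l-th column of the theta matrix as a differentiable vector node
theta_col <- function(tape, theta, l) {
  v <- theta$value[, l]
  n <- length(v)
  ad_node(v, tape = tape, backward = function(g) {
    gm <- matrix(0, n, ncol(theta$value))
    gm[, l] <- g
    ad_acc(theta, gm)
  })
}

#' Run the model on one image stack (inference)
#'
#' Pads inputs to the encoder's divisibility requirement, runs an
#' evaluation-mode forward pass and returns plain matrices.
#'
#' @param model an [mfafn_build()] model.
#' @param images list of N co-registered H x W matrices in \[0,1\].
#' @return list with `seg_probs` and `fused` (padded-size H x W matrices) and
#'   `weights` (L x N fusion weight matrix).
#' @export
mfafn_predict <- function(model, images) {
  m <- 2L^(model$config$encoder$levels - 1L)
  padded <- lapply(images, function(im) pad_to_multiple(as.matrix(im), m)$image)
  out <- mfafn_forward(model, padded, tape = NULL, training = FALSE)
  d <- dim(out$seg$value)
  list(seg_probs = matrix(out$seg$value, d[1L], d[2L]),
       fused = matrix(out$fused$value, d[1L], d[2L]),
       weights = out$weights)
}
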