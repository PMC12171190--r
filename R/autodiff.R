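# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Feature tensors are 4-D arrays with dim (H, W, C, B). A "node" is an
# environment holding the forward value, an accumulated gradient, and a
# backward closure; a "tape" records op nodes in creation order so that
# traversing it in reverse performs backpropagation. Parameters are leaf
# nodes reused across steps; intermediate nodes are created per forward pass.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$ops <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_record <- function(tape, nd) {
  if (is.null(tape)) return(invisible(nd))
  n <- tape$n + 1L
  if (n > length(tape$ops)) tape$ops <- c(tape$ops, vector("list", length(tape$ops)))
  tape$ops[[n]] <- nd
  tape$n <- n
  invisible(nd)
}

#' @noRd
ad_node <- function(value, backward = NULL, tape = NULL, track = !is.null(backward)) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  nd$track <- track
  ad_record(tape, nd)
  nd
}

ad_param <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- NULL
  nd$track <- TRUE
  nd
}

ad_const <- function(value) ad_node(value, backward = NULL, tape = NULL, track = FALSE)

ad_is_node <- function(x) is.environment(x) && !is.null(x$value)

# accumulate gradient g into node nd (no-op for untracked constants)
ad_acc <- function(nd, g) {
  if (!isTRUE(nd$track)) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# run backpropagation from scalar root over the tape
ad_backward <- function(tape, root) {
  root$grad <- 1
  if (tape$n == 0L) return(invisible(NULL))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$ops[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ops --------------------------------------------------------

nd_add <- function(tape, a, b) {
  out <- ad_node(a$value + b$value, tape = tape, backward = function(g) {
    ad_acc(a, g); ad_acc(b, g)
  })
  out
}

nd_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(av * bv, tape = tape, backward = function(g) {
    ad_acc(a, g * bv); ad_acc(b, g * av)
  })
}

nd_gelu <- function(tape, x) {
  fw <- cpp_gelu_fwd(x$value)
  ad_node(fw$y, tape = tape, backward = function(g) {
    ad_acc(x, cpp_gelu_bwd(x$value, fw$phi, g))
  })
}

nd_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, tape = tape, backward = function(g) {
    ad_acc(x, g * s * (1 - s))
  })
}

# out = a + alpha * b, alpha a scalar parameter node
nd_axpy <- function(tape, a, b, alpha) {
  av <- a$value; bv <- b$value; al <- as.numeric(alpha$value)
  ad_node(av + al * bv, tape = tape, backward = function(g) {
    ad_acc(a, g)
    ad_acc(b, al * g)
    ad_acc(alpha, sum(g * bv))
  })
}

# channel concatenation of (H, W, Ca, B) and (H, W, Cb, B)
nd_concat_c <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  ca <- da[3L]
  val <- array(0, c(da[1L], da[2L], ca + db[3L], da[4L]))
  val[, , seq_len(ca), ] <- a$value
  val[, , ca + seq_len(db[3L]), ] <- b$value
  ad_node(val, tape = tape, backward = function(g) {
    ad_acc(a, g[, , seq_len(ca), , drop = FALSE])
    ad_acc(b, g[, , ca + seq_len(db[3L]), , drop = FALSE])
  })
}

# elementwise mean over a list of equally shaped nodes
nd_mean_maps <- function(tape, maps) {
  n <- length(maps)
  val <- maps[[1L]]$value
  if (n > 1L) for (i in 2:n) val <- val + maps[[i]]$value
  val <- val / n
  ad_node(val, tape = tape, backward = function(g) {
    gi <- g / n
    for (m in maps) ad_acc(m, gi)
  })
}

# weighted sum over N maps; w is either a numeric vector (detached weights)
# or a node carrying an N-vector
nd_weighted_sum <- function(tape, maps, w) {
  wn <- if (ad_is_node(w)) w else NULL
  wv <- if (is.null(wn)) w else as.numeric(wn$value)
  val <- wv[1L] * maps[[1L]]$value
  n <- length(maps)
  if (n > 1L) for (i in 2:n) val <- val + wv[i] * maps[[i]]$value
  ad_node(val, tape = tape, backward = function(g) {
    for (i in seq_len(n)) ad_acc(maps[[i]], wv[i] * g)
    if (!is.null(wn)) {
      gw <- vapply(maps, function(m) sum(g * m$value), numeric(1))
      ad_acc(wn, gw)
    }
  })
}

# Group-wise weighted sum over modalities for a modality-batched tensor.
# x holds N modality blocks along the batch axis: slice (i-1)*B + b is
# modality i of sample b. w is either an N x B numeric matrix (detached
# per-sample weights), or a node carrying an N-vector shared across samples.
# Returns (H, W, C, B).
nd_group_wsum <- function(tape, x, w, N, B) {
  wn <- if (ad_is_node(w)) w else NULL
  wv <- if (is.null(wn)) w else matrix(as.numeric(wn$value), N, B)
  val <- cpp_group_wsum_fwd(x$value, wv, N, B)
  ad_node(val, tape = tape, backward = function(g) {
    bw <- cpp_group_wsum_bwd(x$value, wv, g, N, B,
                             isTRUE(x$track), !is.null(wn))
    if (isTRUE(x$track)) ad_acc(x, bw$gx)
    if (!is.null(wn)) ad_acc(wn, rowSums(bw$gw))
  })
}

# mean absolute forward-difference gradient per batch slice of (H, W, C, B)
saliency_per_slice <- function(x) {
  cpp_saliency_slices(x)
}

# fused attention block: spatial-softmax of a bias-free 1x1 channel mix,
# applied multiplicatively with optional residual (out = f + a*f)
nd_attention <- function(tape, f, watt, residual) {
  C <- dim(f$value)[3L]
  wm <- matrix(watt$value, C, C)
  fw <- cpp_attention_fwd(f$value, wm, residual)
  ad_node(fw$out, tape = tape, backward = function(g) {
    bw <- cpp_attention_bwd(f$value, wm, fw$a, g, residual, isTRUE(f$track))
    ad_acc(watt, array(bw$gw, dim(watt$value)))
    if (isTRUE(f$track)) ad_acc(f, bw$gf)
  })
}

# fused context gate + alpha refinement:
# out = F + alpha * sigmoid(1x1conv([F; G0])) * G0
nd_gate_refine <- function(tape, fsd, glob, wg, bg, alpha) {
  C <- dim(fsd$value)[3L]
  wm <- matrix(wg$value, 2L * C, C)
  al <- as.numeric(alpha$value)
  fw <- cpp_gate_refine_fwd(fsd$value, glob$value, wm, bg$value, al)
  ad_node(fw$out, tape = tape, backward = function(g) {
    bw <- cpp_gate_refine_bwd(fsd$value, glob$value, fw$gate, wm, al, g)
    ad_acc(wg, array(bw$gw, dim(wg$value)))
    ad_acc(bg, bw$gb)
    ad_acc(alpha, bw$galpha)
    ad_acc(fsd, bw$gfsd)
    ad_acc(glob, bw$gglob)
  })
}

# softmax over a small vector parameter (per-scale learned fusion weights)
nd_softmax_vec <- function(tape, theta) {
  z <- as.numeric(theta$value)
  e <- exp(z - max(z))
  s <- e / sum(e)
  ad_node(s, tape = tape, backward = function(g) {
    ad_acc(theta, s * (g - sum(g * s)))
  })
}

# softmax over spatial locations, independently per channel and batch element
nd_softmax_spatial <- function(tape, x) {
  a <- cpp_softmax_spatial(x$value)
  ad_node(a, tape = tape, backward = function(g) {
    ad_acc(x, cpp_softmax_spatial_bwd(a, g))
  })
}

# ---- convolutions (C++ kernels in src/conv.cpp) -----------------------------

# 2-D convolution; x (H,W,Ci,B), w (k,k,Ci,Co), b length Co or NULL.
# When recorded on a tape the im2col patch matrix is kept for the backward
# pass (memory for speed).
nd_conv2d <- function(tape, x, w, b = NULL, stride = 1L, pad = 1L) {
  stopifnot(dim(x$value)[3L] == dim(w$value)[3L])
  fw <- cpp_conv2d_fwd(x$value, w$value,
                       if (is.null(b)) NULL else b$value,
                       as.integer(stride), as.integer(pad),
                       keep_p = !is.null(tape))
  ad_node(fw$y, tape = tape, backward = function(g) {
    gr <- cpp_conv2d_bwd(x$value, w$value, g, as.integer(stride),
                         as.integer(pad), isTRUE(x$track), fw$P)
    ad_acc(w, gr$gw)
    if (!is.null(b)) ad_acc(b, gr$gb)
    if (isTRUE(x$track)) ad_acc(x, gr$gx)
  })
}

# transposed convolution, kernel 2, stride 2 (exact x2 upsampling)
nd_convt2d <- function(tape, x, w, b = NULL) {
  val <- cpp_convt2d_fwd(x$value, w$value, if (is.null(b)) NULL else b$value)
  ad_node(val, tape = tape, backward = function(g) {
    gr <- cpp_convt2d_bwd(x$value, w$value, g, isTRUE(x$track), !is.null(b))
    ad_acc(w, gr$gw)
    if (!is.null(b)) ad_acc(b, gr$gb)
    if (isTRUE(x$track)) ad_acc(x, gr$gx)
  })
}

# ---- batch normalization ----------------------------------------------------

bn_state <- function(channels) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(channels)
  st$var <- rep(1, channels)
  st
}

# fused batch-normalization + GELU (the conv-block motif); one kernel each way
nd_bn_gelu <- function(tape, x, gamma, beta, state, training,
                       momentum = 0.1, eps = 1e-5) {
  fw <- cpp_bn_gelu_fwd(x$value, gamma$value, beta$value, state$mean,
                        state$var, use_batch_stats = training, eps = eps)
  if (training) {
    state$mean <- (1 - momentum) * state$mean + momentum * fw$mean
    state$var <- (1 - momentum) * state$var + momentum * fw$var
  }
  var_used <- fw$var
  ad_node(fw$y, tape = tape, backward = function(g) {
    bw <- cpp_bn_gelu_bwd(g, fw$xhat, fw$s, gamma$value, beta$value,
                          var_used, eps, training, isTRUE(x$track))
    ad_acc(gamma, bw$ggamma)
    ad_acc(beta, bw$gbeta)
    if (isTRUE(x$track)) ad_acc(x, bw$gx)
  })
}

# per-channel normalization over (H, W, B); population statistics
nd_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  fw <- cpp_bn_fwd(x$value, gamma$value, beta$value, state$mean, state$var,
                   use_batch_stats = training, eps = eps)
  if (training) {
    state$mean <- (1 - momentum) * state$mean + momentum * fw$mean
    state$var <- (1 - momentum) * state$var + momentum * fw$var
  }
  var_used <- fw$var
  ad_node(fw$y, tape = tape, backward = function(g) {
    bw <- cpp_bn_bwd(g, fw$xhat, gamma$value, var_used, eps, training,
                     isTRUE(x$track))
    ad_acc(gamma, bw$ggamma)
    ad_acc(beta, bw$gbeta)
    if (isTRUE(x$track)) ad_acc(x, bw$gx)
  })
}

# ---- segmentation loss ------------------------------------------------------

# w_dice*(1 - softDice) + w_ce*BCE; soft Dice per batch sample then averaged,
# BCE averaged over all pixels; probs clamped only inside the logs
nd_seg_loss <- function(tape, p, target, w_dice = 0.5, w_ce = 0.5, eps = 1e-7) {
  pv <- p$value
  tv <- target
  d <- dim(pv)
  B <- d[4L]
  npx <- d[1L] * d[2L] * d[3L]
  pm <- matrix(pv, npx, B)
  tm <- matrix(tv, npx, B)
  A <- colSums(pm * tm)
  S <- colSums(pm) + colSums(tm)
  dice <- ifelse(S > 0, 2 * A / S, 1)
  pc <- pmin(pmax(pm, eps), 1 - eps)
  bce <- -mean(tm * log(pc) + (1 - tm) * log(1 - pc))
  loss <- w_dice * (1 - mean(dice)) + w_ce * bce
  ad_node(loss, tape = tape, backward = function(g) {
    gdice <- matrix(0, npx, B)
    for (b in seq_len(B)) {
      if (S[b] > 0) gdice[, b] <- (2 * tm[, b] * S[b] - 2 * A[b]) / (S[b]^2)
    }
    gp <- -w_dice * gdice / B +
      w_ce * (-(tm / pc) + (1 - tm) / (1 - pc)) / (npx * B)
    ad_acc(p, g * array(gp, d))
  })
}

# ---- Adam optimizer ---------------------------------------------------------

adam_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) array(0, dim(as.array(p$value))))
  st$v <- lapply(params, function(p) array(0, dim(as.array(p$value))))
  st$t <- 0L
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, lr) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    mhat <- st$m[[i]] / bc1
    vhat <- st$v[[i]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + st$eps)
  }
  ad_zero_grads(st$params)
  invisible(NULL)
}
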