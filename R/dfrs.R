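# Dynamic feature refinement: gradient-based saliency scores, softmax fusion
# weights, global context aggregation, concatenation-gated context attention,
# and the alpha-gated refinement update.

#' Gradient-L1 saliency of a feature map
#'
#' Forward-difference spatial gradients in both axes with replicate borders
#' (so the last row/column difference is zero); the absolute values are summed
#' over all positions and channels and divided by the element count H*W*C.
#' The size normalization keeps the downstream softmax away from saturation
#' while preserving the ordering of same-sized maps.
#'
#' @param feature_map H x W x C array (or H x W matrix).
#' @return nonnegative scalar; 0 iff the map is spatially constant.
#' @export
saliency <- function(feature_map) {
  f <- as_feature_map(feature_map)
  d <- dim(f)
  if (!all(is.finite(f))) stop("saliency: non-finite feature map", call. = FALSE)
  total <- 0
  if (d[1L] > 1L) {
    total <- total + sum(abs(f[2:d[1L], , , drop = FALSE] - f[seq_len(d[1L] - 1L), , , drop = FALSE]))
  }
  if (d[2L] > 1L) {
    total <- total + sum(abs(f[, 2:d[2L], , drop = FALSE] - f[, seq_len(d[2L] - 1L), , drop = FALSE]))
  }
  total / prod(d)
}

#' Softmax fusion weights from saliency scores
#'
#' `w_i = exp(s_i) / sum_j exp(s_j)` with max-subtraction stabilization.
#'
#' @param scores numeric vector of N >= 1 finite saliency scores.
#' @return N-vector on the probability simplex.
#' @export
saliency_weights <- function(scores) {
  if (length(scores) < 1L) stop("saliency_weights: empty score vector", call. = FALSE)
  if (!all(is.finite(scores))) stop("saliency_weights: non-finite scores", call. = FALSE)
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Global context: elementwise mean over input feature maps
#'
#' @param maps list of N equally shaped arrays.
#' @return array of the same shape.
#' @export
global_context <- function(maps) {
  if (length(maps) < 1L) stop("global_context: empty map list", call. = FALSE)
  maps <- lapply(maps, as_feature_map)
  d <- dim(maps[[1L]])
  for (m in maps) {
    if (!identical(dim(m), d)) stop("global_context: shape mismatch", call. = FALSE)
  }
  Reduce(`+`, maps) / length(maps)
}

#' Default (zero) parameters for the context-attention gate
#'
#' @param channels feature channel count C.
#' @return list with `w` (2C x C zero matrix) and `b` (length-C zero vector);
#'   zero parameters give a gate of exactly 0.5 everywhere.
#' @export
context_gate_params <- function(channels) {
  list(w = matrix(0, 2L * channels, channels), b = numeric(channels))
}

#' Context-aware refinement signal
#'
#' Gate = logistic(1 x 1 convolution over the channel concatenation
#' `[fused; context]`); the signal is `gate * context`, so it is bounded by
#' the context in absolute value at every element.
#'
#' @param fused H x W x C fused feature map.
#' @param context H x W x C global context map.
#' @param params gate parameters as from [context_gate_params()]; `w` is
#'   2C x C, `b` length C. Defaults to zeros.
#' @return refinement signal, same shape as `context`.
#' @export
context_attention <- function(fused, context, params = NULL) {
  f <- as_feature_map(fused)
  g <- as_feature_map(context)
  if (!identical(dim(f), dim(g))) {
    stop("context_attention: shape mismatch between fused map and context", call. = FALSE)
  }
  d <- dim(f)
  if (is.null(params)) params <- context_gate_params(d[3L])
  if (nrow(params$w) != 2L * d[3L] || ncol(params$w) != d[3L]) {
    stop("context_attention: gate weights must be ", 2L * d[3L], " x ", d[3L],
         call. = FALSE)
  }
  cat_m <- cbind(matrix(f, d[1L] * d[2L], d[3L]), matrix(g, d[1L] * d[2L], d[3L]))
  logits <- sweep(cat_m %*% params$w, 2L, params$b, "+")
  gate <- 1 / (1 + exp(-logits))
  array(gate, d) * g
}

#' Alpha-gated refinement update
#'
#' `F + alpha * G`; with `alpha = 0` (its initialization) the update is the
#' identity, so the refinement path is provably harmless at start.
#'
#' @param fused H x W x C fused feature map.
#' @param signal refinement signal of identical shape.
#' @param alpha scalar gate.
#' @return refined feature map.
#' @export
refine <- function(fused, signal, alpha = 0) {
  f <- as_feature_map(fused)
  g <- as_feature_map(signal)
  if (!identical(dim(f), dim(g))) stop("refine: shape mismatch", call. = FALSE)
  f + alpha * g
}
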