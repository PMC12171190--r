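# Attention-driven feature alignment: per-scale importance maps from a 1x1
# channel-mixing transform followed by a softmax over spatial locations, and
# residual attention modulation of the feature maps.

# coerce an H x W (x C) input to (H, W, C)
as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  x
}

#' Compute a spatial-softmax attention map
#'
#' Each pixel's C-vector is transformed by the C x C weight matrix (a
#' bias-free 1 x 1 convolution), then a softmax is taken over the spatial
#' locations independently per channel, so each channel of the result is a
#' probability distribution over the H x W grid.
#'
#' @param feature_map H x W x C array (or H x W matrix for C = 1).
#' @param weights C x C matrix; row c gives the mixing weights producing
#'   output channel c.
#' @return H x W x C array; nonnegative, each channel sums to 1.
#' @export
compute_attention <- function(feature_map, weights) {
  f <- as_feature_map(feature_map)
  d <- dim(f)
  if (!all(is.finite(f))) stop("compute_attention: non-finite feature map", call. = FALSE)
  weights <- as.matrix(weights)
  if (nrow(weights) != d[3L] || ncol(weights) != d[3L]) {
    stop("compute_attention: weights must be ", d[3L], " x ", d[3L], call. = FALSE)
  }
  fm <- matrix(f, d[1L] * d[2L], d[3L])
  logits <- fm %*% t(weights)
  mx <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, mx, "-"))
  a <- sweep(e, 2L, colSums(e), "/")
  array(a, d)
}

#' Apply (residual) attention modulation
#'
#' With `residual = FALSE` returns `A * F` (elementwise); with
#' `residual = TRUE` returns `F + A * F`, retaining the unmodulated features.
#'
#' @param feature_map H x W x C array.
#' @param attention attention map of identical shape.
#' @param residual logical flag.
#' @return modulated feature map, same shape.
#' @export
apply_residual_attention <- function(feature_map, attention, residual = TRUE) {
  f <- as_feature_map(feature_map)
  a <- as_feature_map(attention)
  if (!identical(dim(f), dim(a))) {
    stop("apply_residual_attention: shape mismatch between features and attention",
         call. = FALSE)
  }
  if (residual) f + a * f else a * f
}
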