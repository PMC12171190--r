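# Per-scale adaptive weighted fusion and the classical Laplacian-pyramid
# fusion baseline.

#' Fuse aligned feature maps with simplex weights
#'
#' Exact weighted sum `sum_i w_i * F_i`; the weights must lie on the
#' probability simplex to within 1e-6.
#'
#' @param aligned_maps list of N equally shaped arrays.
#' @param weights numeric N-vector on the simplex.
#' @return fused array of the shared shape.
#' @export
fuse_scale <- function(aligned_maps, weights) {
  n <- length(aligned_maps)
  if (length(weights) != n) {
    stop("fuse_scale: ", n, " maps but ", length(weights), " weights", call. = FALSE)
  }
  if (any(weights < -1e-6) || abs(sum(weights) - 1) > 1e-6) {
    stop("fuse_scale: weights must lie on the probability simplex (sum 1, nonnegative)",
         call. = FALSE)
  }
  maps <- lapply(aligned_maps, as_feature_map)
  d <- dim(maps[[1L]])
  out <- array(0, d)
  for (i in seq_len(n)) {
    if (!identical(dim(maps[[i]]), d)) stop("fuse_scale: shape mismatch", call. = FALSE)
    out <- out + weights[i] * maps[[i]]
  }
  out
}

#' Learned fusion weights via softmax
#'
#' Maps N free real parameters (per scale) onto the probability simplex by a
#' softmax, guaranteeing the sum-to-one constraint by construction.
#'
#' @param params numeric N-vector, or N x L matrix (one column per scale).
#' @return weights of the same shape, each (column) on the simplex.
#' @export
learned_weights <- function(params) {
  if (is.matrix(params)) {
    apply(params, 2L, function(z) {
      e <- exp(z - max(z)); e / sum(e)
    })
  } else {
    if (!all(is.finite(params))) stop("learned_weights: non-finite parameters", call. = FALSE)
    e <- exp(params - max(params))
    e / sum(e)
  }
}

# ---- Laplacian-pyramid baseline ---------------------------------------------

# Burt-Adelson 5-tap generating kernel
.lp_kernel <- c(1, 4, 6, 4, 1) / 16

.lp_blur <- function(img) {
  conv2_replicate(img, outer(.lp_kernel, .lp_kernel))
}

.lp_down <- function(img) {
  b <- .lp_blur(img)
  b[seq(1L, nrow(b), 2L), seq(1L, ncol(b), 2L), drop = FALSE]
}

.lp_up <- function(img, target_dim) {
  up <- matrix(0, target_dim[1L], target_dim[2L])
  up[seq(1L, target_dim[1L], 2L), seq(1L, target_dim[2L], 2L)] <-
    img[seq_len(ceiling(target_dim[1L] / 2)), seq_len(ceiling(target_dim[2L] / 2)), drop = FALSE]
  4 * .lp_blur(up)
}

# build a Laplacian pyramid: detail levels 1..(levels-1) plus lowpass residual
laplacian_pyramid <- function(img, levels) {
  g <- img
  pyr <- vector("list", levels)
  if (levels > 1L) {
    for (l in seq_len(levels - 1L)) {
      gn <- .lp_down(g)
      pyr[[l]] <- g - .lp_up(gn, dim(g))
      g <- gn
    }
  }
  pyr[[levels]] <- g
  pyr
}

laplacian_reconstruct <- function(pyr) {
  levels <- length(pyr)
  g <- pyr[[levels]]
  if (levels > 1L) {
    for (l in seq(levels - 1L, 1L)) {
      g <- pyr[[l]] + .lp_up(g, dim(pyr[[l]]))
    }
  }
  g
}

#' Classical Laplacian-pyramid fusion baseline
#'
#' Decomposes each input into a Laplacian pyramid, fuses detail coefficients
#' by the maximum-absolute-value rule across inputs (lowpass residual: mean),
#' and reconstructs with the inverse transform. With a single input the
#' transform/inverse pair is a perfect-reconstruction identity.
#'
#' @param images list of N >= 1 equally sized H x W matrices.
#' @param levels pyramid depth (including the lowpass residual).
#' @return fused H x W matrix.
#' @export
laplacian_fuse <- function(images, levels = 4L) {
  n <- length(images)
  if (n < 1L) stop("laplacian_fuse: empty image list", call. = FALSE)
  d <- dim(images[[1L]])
  levels <- as.integer(levels)
  if (min(d) / 2^(levels - 1L) < 2) {
    stop("laplacian_fuse: ", levels, " levels is too deep for a ",
         d[1L], " x ", d[2L], " image", call. = FALSE)
  }
  pyrs <- lapply(images, laplacian_pyramid, levels = levels)
  fused <- vector("list", levels)
  if (levels > 1L) {
    for (l in seq_len(levels - 1L)) {
      stack <- vapply(pyrs, function(p) p[[l]], pyrs[[1L]][[l]])
      dim(stack) <- c(dim(pyrs[[1L]][[l]]), n)
      pick <- apply(abs(stack), c(1L, 2L), which.max)
      fused[[l]] <- matrix(stack[cbind(as.vector(row(pick)), as.vector(col(pick)),
                                       as.vector(pick))],
                           nrow(pick), ncol(pick))
    }
  }
  low <- Reduce(`+`, lapply(pyrs, function(p) p[[levels]])) / n
  fused[[levels]] <- low
  laplacian_reconstruct(fused)
}
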