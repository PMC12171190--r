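# Fusion-quality metrics (SSIM-based spatial consistency, histogram entropy,
# gradient alignment) and segmentation overlap metrics.

#' Structural similarity index (SSIM) between two images
#'
#' Gaussian-window SSIM with the original defaults: window 11, sigma 1.5,
#' K1 = 0.01, K2 = 0.03, dynamic range 1. Windowing uses replicate borders.
#'
#' @param x,y equally sized H x W matrices in \[0,1\].
#' @return mean SSIM over the image.
#' @export
ssim <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("ssim: size mismatch", call. = FALSE)
  C1 <- 0.01^2; C2 <- 0.03^2
  ker <- gaussian_kernel(11L, 1.5)
  mu_x <- conv2_replicate(x, ker)
  mu_y <- conv2_replicate(y, ker)
  sxx <- conv2_replicate(x * x, ker) - mu_x^2
  syy <- conv2_replicate(y * y, ker) - mu_y^2
  sxy <- conv2_replicate(x * y, ker) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * sxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Spatial consistency of a fused image
#'
#' Sum of SSIM(fused, input_i) over the N inputs; its maximum is N, so the
#' N-normalized mean is returned alongside.
#'
#' @param fused H x W matrix.
#' @param inputs list of N co-registered H x W matrices.
#' @return list with `q_spatial` (raw sum) and `q_spatial_norm` (sum / N).
#' @export
q_spatial <- function(fused, inputs) {
  vals <- vapply(inputs, function(im) {
    if (!identical(dim(im), dim(fused))) stop("q_spatial: size mismatch", call. = FALSE)
    ssim(fused, im)
  }, numeric(1))
  list(q_spatial = sum(vals), q_spatial_norm = sum(vals) / length(vals))
}

#' Histogram entropy of an image (bits)
#'
#' Shannon entropy (base 2) of the `bins`-bin intensity histogram on \[0,1\];
#' empty bins contribute 0.
#'
#' @param image H x W matrix in \[0,1\].
#' @param bins number of histogram bins (>= 2).
#' @return entropy in bits, in \[0, log2(bins)\].
#' @export
q_info <- function(image, bins = 256L) {
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("q_info: bins must be >= 2", call. = FALSE)
  idx <- pmin(floor(pmin(pmax(image, 0), 1) * bins) + 1L, bins)
  p <- tabulate(idx, nbins = bins) / length(image)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# forward-difference gradient pair with replicate borders (last row/col 0)
.fdiff <- function(img) {
  H <- nrow(img); W <- ncol(img)
  dx <- rbind(img[-1L, , drop = FALSE] - img[-H, , drop = FALSE], rep(0, W))
  dy <- cbind(img[, -1L, drop = FALSE] - img[, -W, drop = FALSE], rep(0, H))
  list(dx = dx, dy = dy)
}

#' Gradient-alignment cost of a fused image
#'
#' `sum_i ||grad F - grad I_i||_2^2` with forward-difference gradients
#' (replicate borders), matching the saliency gradient operator. Lower is
#' better; zero iff the fused gradients equal every input's gradients.
#'
#' @param fused H x W matrix.
#' @param inputs list of N co-registered H x W matrices.
#' @return nonnegative scalar.
#' @export
q_edge <- function(fused, inputs) {
  gf <- .fdiff(fused)
  sum(vapply(inputs, function(im) {
    if (!identical(dim(im), dim(fused))) stop("q_edge: size mismatch", call. = FALSE)
    gi <- .fdiff(im)
    sum((gf$dx - gi$dx)^2) + sum((gf$dy - gi$dy)^2)
  }, numeric(1)))
}

#' Segmentation overlap metrics
#'
#' Dice, IoU, Precision and Recall between binary masks. When both masks are
#' empty all four metrics are 1; otherwise a metric whose denominator set is
#' empty is 0.
#'
#' @param pred_mask,truth_mask equally shaped binary (\{0,1\}) matrices.
#' @return object of class `metric_report`: named list of the four metrics
#'   plus the pixel counts used.
#' @export
seg_metrics <- function(pred_mask, truth_mask) {
  if (!identical(dim(pred_mask), dim(truth_mask))) {
    stop("seg_metrics: shape mismatch", call. = FALSE)
  }
  if (!all(pred_mask %in% c(0, 1)) || !all(truth_mask %in% c(0, 1))) {
    stop("seg_metrics: masks must be binary {0,1}", call. = FALSE)
  }
  tp <- sum(pred_mask == 1 & truth_mask == 1)
  np <- sum(pred_mask == 1)
  nt <- sum(truth_mask == 1)
  un <- np + nt - tp
  if (np == 0 && nt == 0) {
    vals <- c(dice = 1, iou = 1, precision = 1, recall = 1)
  } else {
    vals <- c(dice = if (np + nt > 0) 2 * tp / (np + nt) else 0,
              iou = if (un > 0) tp / un else 0,
              precision = if (np > 0) tp / np else 0,
              recall = if (nt > 0) tp / nt else 0)
  }
  structure(list(metrics = vals,
                 counts = c(tp = tp, pred = np, truth = nt, union = un)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics:\n")
  for (nm in names(x$metrics)) {
    cat(sprintf("  %-9s %.4f\n", nm, x$metrics[[nm]]))
  }
  invisible(x)
}

#' Full fusion-quality report for a fused image
#'
#' @param fused H x W matrix in \[0,1\].
#' @param inputs list of N co-registered input images.
#' @param bins entropy histogram bins.
#' @return named list: `q_spatial`, `q_spatial_norm`, `q_info`, `q_edge`.
#' @export
fusion_quality <- function(fused, inputs, bins = 256L) {
  qs <- q_spatial(fused, inputs)
  c(qs, list(q_info = q_info(fused, bins), q_edge = q_edge(fused, inputs)))
}
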