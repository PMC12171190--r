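# Intensity normalization and cross-modality calibration applied to input
# stacks before encoding. Two normalizations are offered: min-max to [0,1]
# for raw loading, and z-score (zero mean, unit population variance) followed
# by histogram-matching calibration on the refinement path.

#' Min-max normalization to \[0,1\]
#'
#' `(I - min(I)) / (max(I) - min(I))`.
#'
#' @param image finite numeric matrix/array.
#' @param index optional image index used in the error message for constant
#'   images.
#' @return normalized image spanning exactly \[0,1\].
#' @export
minmax_normalize <- function(image, index = NULL) {
  if (!all(is.finite(image))) stop("minmax_normalize: non-finite values", call. = FALSE)
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    stop("minmax_normalize: constant image",
         if (!is.null(index)) paste0(" (index ", index, ")") else "",
         " has no intensity range", call. = FALSE)
  }
  (image - lo) / (hi - lo)
}

#' Z-score normalization (population standard deviation)
#'
#' `(I - mean(I)) / sd_pop(I)`; the output has mean 0 and population standard
#' deviation 1.
#'
#' @inheritParams minmax_normalize
#' @export
zscore_normalize <- function(image, index = NULL) {
  if (!all(is.finite(image))) stop("zscore_normalize: non-finite values", call. = FALSE)
  mu <- mean(image)
  sd_pop <- sqrt(mean((image - mu)^2))
  if (sd_pop == 0) {
    stop("zscore_normalize: constant image",
         if (!is.null(index)) paste0(" (index ", index, ")") else "",
         " has zero variance", call. = FALSE)
  }
  (image - mu) / sd_pop
}

#' Normalize a stack of co-registered images
#'
#' @param images list of H x W matrices.
#' @param method `"minmax"` or `"zscore"`.
#' @return object of class `normalized_stack`: `images`, `method`, and
#'   per-image statistics (`min`/`max` or `mean`/`sd`).
#' @export
normalize_stack <- function(images, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  if (length(images) < 1L) stop("normalize_stack: empty stack", call. = FALSE)
  stats_list <- vector("list", length(images))
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (method == "minmax") {
      out[[i]] <- minmax_normalize(img, index = i)
      stats_list[[i]] <- c(min = min(img), max = max(img))
    } else {
      out[[i]] <- zscore_normalize(img, index = i)
      stats_list[[i]] <- c(mean = mean(img), sd = sqrt(mean((img - mean(img))^2)))
    }
  }
  structure(list(images = out, method = method, per_image_stats = stats_list),
            class = "normalized_stack")
}

#' Calibrate a normalized stack by histogram matching to the pooled distribution
#'
#' Each image is remapped by a monotone, rank-preserving intensity map onto
#' the reference distribution formed by pooling all N images' intensities
#' (a predefined, parameter-free instance of a dynamic intensity mapping).
#' With N = 1 the stack is returned unchanged.
#'
#' @param stack a `normalized_stack` or plain list of H x W matrices.
#' @return same type as the input, with calibrated images.
#' @export
calibrate_stack <- function(stack) {
  is_ns <- inherits(stack, "normalized_stack")
  images <- if (is_ns) stack$images else stack
  if (length(images) == 0L) stop("calibrate_stack: empty stack", call. = FALSE)
  if (length(images) == 1L) return(stack)
  pooled <- sort(unlist(lapply(images, as.vector)))
  np <- length(pooled)
  out <- lapply(images, function(img) {
    n <- length(img)
    # mid-rank quantile position of each pixel within its own image,
    # mapped to the pooled order statistics (monotone, rank-preserving)
    r <- rank(img, ties.method = "average")
    q <- pooled[pmin(pmax(round((r - 0.5) / n * np + 0.5), 1), np)]
    matrix(q, nrow(img), ncol(img))
  })
  if (is_ns) {
    stack$images <- out
    stack
  } else out
}
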