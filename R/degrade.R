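#' Degradation specification
#'
#' One simulated clinical acquisition degradation. Exactly one `kind` applies;
#' parameters irrelevant to that kind are ignored. The condition set mirrors a
#' robustness benchmark of low light, JPEG compression artifacts (quality 30),
#' Gaussian "motion" blur (5 x 5 kernel) and additive Gaussian noise
#' (sigma = 0.05).
#'
#' @param kind one of `"none"`, `"low_light"`, `"jpeg"`, `"motion_blur"`,
#'   `"gaussian_noise"`.
#' @param jpeg_quality integer in \[1, 100\].
#' @param blur_kernel odd kernel size in pixels.
#' @param blur_sigma Gaussian blur standard deviation (> 0).
#' @param noise_sigma additive noise standard deviation (>= 0).
#' @param low_light_gain multiplicative gain in (0, 1].
#' @param low_light_gamma gamma exponent (>= 1), darkens shadows.
#' @return object of class `degradation_spec`.
#' @export
degradation_spec <- function(kind = c("none", "low_light", "jpeg",
                                      "motion_blur", "gaussian_noise"),
                             jpeg_quality = 30L, blur_kernel = 5L,
                             blur_sigma = 1.0, noise_sigma = 0.05,
                             low_light_gain = 0.35, low_light_gamma = 1.5) {
  kind <- match.arg(kind)
  jpeg_quality <- as.integer(jpeg_quality)
  blur_kernel <- as.integer(blur_kernel)
  if (kind == "jpeg" && (is.na(jpeg_quality) || jpeg_quality < 1L || jpeg_quality > 100L)) {
    stop("degradation_spec: jpeg_quality must lie in [1, 100]", call. = FALSE)
  }
  if (kind == "motion_blur") {
    if (is.na(blur_kernel) || blur_kernel %% 2L == 0L || blur_kernel < 1L) {
      stop("degradation_spec: blur_kernel must be odd and positive", call. = FALSE)
    }
    if (!is.numeric(blur_sigma) || blur_sigma <= 0) {
      stop("degradation_spec: blur_sigma must be > 0", call. = FALSE)
    }
  }
  if (kind == "gaussian_noise" && (!is.numeric(noise_sigma) || noise_sigma < 0)) {
    stop("degradation_spec: noise_sigma must be >= 0", call. = FALSE)
  }
  if (kind == "low_light" &&
      (!is.numeric(low_light_gain) || low_light_gain <= 0 || low_light_gain > 1)) {
    stop("degradation_spec: low_light_gain must lie in (0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, jpeg_quality = jpeg_quality,
                 blur_kernel = blur_kernel, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, low_light_gain = low_light_gain,
                 low_light_gamma = low_light_gamma),
            class = "degradation_spec")
}

#' The standard robustness condition set
#'
#' @return named list of [degradation_spec()] objects: low light, JPEG Q=30,
#'   Gaussian 5 x 5 blur, Gaussian noise sigma=0.05.
#' @export
standard_conditions <- function() {
  list(low_light = degradation_spec("low_light"),
       jpeg = degradation_spec("jpeg", jpeg_quality = 30L),
       motion_blur = degradation_spec("motion_blur", blur_kernel = 5L, blur_sigma = 1.0),
       gaussian_noise = degradation_spec("gaussian_noise", noise_sigma = 0.05))
}

# normalized k x k Gaussian kernel
gaussian_kernel <- function(k, sigma) {
  r <- (k - 1L) / 2
  g <- stats::dnorm(seq(-r, r), sd = sigma)
  ker <- outer(g, g)
  ker / sum(ker)
}

# 2-D convolution with replicate borders (constant images stay constant)
conv2_replicate <- function(img, ker) {
  k <- nrow(ker)
  r <- (k - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  ri <- c(rep(1L, r), seq_len(H), rep(H, r))
  ci <- c(rep(1L, r), seq_len(W), rep(W, r))
  xp <- img[ri, ci, drop = FALSE]
  out <- matrix(0, H, W)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    out <- out + ker[a, b] * xp[(a - 1L) + seq_len(H), (b - 1L) + seq_len(W), drop = FALSE]
  }
  out
}

#' Apply a degradation to an image
#'
#' `none` is the identity. `low_light` applies `gain * I^gamma` (gamma >= 1).
#' `jpeg` performs an 8-bit quantized JPEG round-trip (8 x 8 block DCT with
#' the standard luminance quantization table scaled by quality). `motion_blur`
#' convolves with a normalized Gaussian kernel (replicate borders).
#' `gaussian_noise` adds N(0, sigma^2) and clips to \[0,1\].
#'
#' @param image H x W matrix with values in \[0,1\].
#' @param spec a [degradation_spec()].
#' @param seed optional integer seed for the stochastic (noise) kind.
#' @return degraded image, same shape, values in \[0,1\].
#' @export
degrade <- function(image, spec, seed = NULL) {
  stopifnot(inherits(spec, "degradation_spec"), is.matrix(image))
  switch(spec$kind,
    none = image,
    low_light = {
      out <- spec$low_light_gain * pmax(image, 0)^spec$low_light_gamma
      pmin(pmax(out, 0), 1)
    },
    jpeg = jpeg_roundtrip(image, spec$jpeg_quality),
    motion_blur = {
      ker <- gaussian_kernel(spec$blur_kernel, spec$blur_sigma)
      pmin(pmax(conv2_replicate(image, ker), 0), 1)
    },
    gaussian_noise = {
      if (spec$noise_sigma == 0) return(image)
      if (!is.null(seed)) {
        old <- .Random.seed_get()
        on.exit(.Random.seed_set(old), add = TRUE)
        set.seed(seed)
      }
      out <- image + matrix(stats::rnorm(length(image), 0, spec$noise_sigma),
                            nrow(image), ncol(image))
      pmin(pmax(out, 0), 1)
    })
}

# standard JPEG luminance quantization table (baseline codec)
.jpeg_qtable <- matrix(c(
  16, 11, 10, 16, 24, 40, 51, 61,
  12, 12, 14, 19, 26, 58, 60, 55,
  14, 13, 16, 24, 40, 57, 69, 56,
  14, 17, 22, 29, 51, 87, 80, 62,
  18, 22, 37, 56, 68, 109, 103, 77,
  24, 35, 55, 64, 81, 104, 113, 92,
  49, 64, 78, 87, 103, 121, 120, 101,
  72, 92, 95, 98, 112, 100, 103, 99), 8, 8, byrow = TRUE)

# orthonormal 8-point DCT-II matrix
.dct8 <- local({
  n <- 8
  D <- matrix(0, n, n)
  for (k in 0:(n - 1)) for (j in 0:(n - 1)) {
    D[k + 1, j + 1] <- cos(pi * (2 * j + 1) * k / (2 * n)) *
      if (k == 0) sqrt(1 / n) else sqrt(2 / n)
  }
  D
})

#' JPEG round-trip compression simulator
#'
#' Applies the lossy core of baseline grayscale JPEG: quantize to 8 bits,
#' level-shift, 8 x 8 block DCT, quantize coefficients with the standard
#' luminance table scaled by `quality` (IJG scaling), dequantize, inverse DCT,
#' and rescale to \[0,1\]. Entropy coding is lossless and therefore omitted.
#' Images are edge-replicated to a multiple of 8 and cropped back.
#'
#' @param image H x W matrix in \[0,1\].
#' @param quality integer in \[1, 100\].
#' @return compressed-and-decompressed image in \[0,1\].
#' @export
jpeg_roundtrip <- function(image, quality) {
  quality <- as.integer(quality)
  if (is.na(quality) || quality < 1L || quality > 100L) {
    stop("jpeg_roundtrip: quality must lie in [1, 100]", call. = FALSE)
  }
  scale <- if (quality < 50L) 5000 / quality else 200 - 2 * quality
  qt <- pmin(pmax(floor((.jpeg_qtable * scale + 50) / 100), 1), 255)
  H <- nrow(image); W <- ncol(image)
  Hp <- 8L * ceiling(H / 8); Wp <- 8L * ceiling(W / 8)
  ri <- c(seq_len(H), rep(H, Hp - H)); ci <- c(seq_len(W), rep(W, Wp - W))
  x <- round(pmin(pmax(image[ri, ci, drop = FALSE], 0), 1) * 255) - 128
  out <- matrix(0, Hp, Wp)
  D <- .dct8
  for (bi in seq_len(Hp / 8)) for (bj in seq_len(Wp / 8)) {
    rows <- (bi - 1L) * 8L + 1:8; cols <- (bj - 1L) * 8L + 1:8
    coef <- D %*% x[rows, cols] %*% t(D)
    coef <- round(coef / qt) * qt
    out[rows, cols] <- t(D) %*% coef %*% D
  }
  out <- round(pmin(pmax(out + 128, 0), 255))
  out[seq_len(H), seq_len(W), drop = FALSE] / 255
}
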