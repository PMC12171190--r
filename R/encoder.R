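# Multi-scale convolutional feature extraction: an L-level encoder producing
# a feature pyramid with spatial size halved and channel depth grown per
# level. Level 1 is at full input resolution; downsampling between levels is
# a stride-2 convolution.

#' Encoder configuration
#'
#' @param levels number of pyramid levels L (>= 1; >= 2 for a true pyramid).
#' @param base_channels channels at level 1.
#' @param kernel_size odd convolution kernel size.
#' @param channel_growth per-level channel growth factor; channels at level l
#'   are `base_channels * channel_growth^(l-1)`.
#' @param in_channels input image channels (1 for grayscale).
#' @param preset `"tiny"` (the CPU test scale) or `"paper"` (four blocks,
#'   base 64 growing to 512). Explicit arguments override the preset.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(levels = 4L, base_channels = 8L, kernel_size = 3L,
                           channel_growth = 2, in_channels = 1L,
                           preset = c("tiny", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper" && missing(base_channels)) base_channels <- 64L
  levels <- as.integer(levels)
  base_channels <- as.integer(base_channels)
  kernel_size <- as.integer(kernel_size)
  if (is.na(levels) || levels < 1L) stop("encoder_config: levels must be >= 1", call. = FALSE)
  if (is.na(base_channels) || base_channels < 1L) {
    stop("encoder_config: base_channels must be >= 1", call. = FALSE)
  }
  if (is.na(kernel_size) || kernel_size %% 2L == 0L) {
    stop("encoder_config: kernel_size must be odd", call. = FALSE)
  }
  channels <- as.integer(round(base_channels * channel_growth^(seq_len(levels) - 1L)))
  structure(list(levels = levels, base_channels = base_channels,
                 kernel_size = kernel_size, channel_growth = channel_growth,
                 in_channels = as.integer(in_channels), channels = channels),
            class = "encoder_config")
}

# He-normal initializer
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build a seeded multi-scale encoder
#'
#' Block 1 is convolution (stride 1, odd kernel, zero "same" padding) ->
#' batch normalization -> GELU at full resolution; each later block is a
#' stride-2 downsampling convolution followed by convolution -> batch
#' normalization -> GELU at the halved resolution.
#'
#' @param config an [encoder_config()].
#' @param seed integer seed for parameter initialization.
#' @return object of class `mfafn_encoder` holding parameter nodes and batch
#'   normalization state.
#' @export
build_encoder <- function(config, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(seed, 101L))
  k <- config$kernel_size
  ch <- config$channels
  params <- list()
  states <- list()
  cin <- config$in_channels
  for (l in seq_len(config$levels)) {
    if (l > 1L) {
      params[[paste0("down", l, "_w")]] <-
        ad_param(he_init(c(k, k, ch[l - 1L], ch[l]), k * k * ch[l - 1L]))
      params[[paste0("down", l, "_b")]] <- ad_param(numeric(ch[l]))
      cin <- ch[l]
    }
    params[[paste0("conv", l, "_w")]] <-
      ad_param(he_init(c(k, k, cin, ch[l]), k * k * cin))
    params[[paste0("conv", l, "_b")]] <- ad_param(numeric(ch[l]))
    params[[paste0("bn", l, "_gamma")]] <- ad_param(rep(1, ch[l]))
    params[[paste0("bn", l, "_beta")]] <- ad_param(numeric(ch[l]))
    states[[paste0("bn", l)]] <- bn_state(ch[l])
    cin <- ch[l]
  }
  structure(list(config = config, params = params, states = states, seed = seed),
            class = "mfafn_encoder")
}

# forward pass through the encoder; x is a node (H, W, in, B)
encoder_forward <- function(enc, x, tape = NULL, training = FALSE) {
  p <- enc$params
  pad <- (enc$config$kernel_size - 1L) %/% 2L
  pyr <- vector("list", enc$config$levels)
  h <- x
  for (l in seq_len(enc$config$levels)) {
    if (l > 1L) {
      h <- nd_conv2d(tape, h, p[[paste0("down", l, "_w")]],
                     p[[paste0("down", l, "_b")]], stride = 2L, pad = pad)
    }
    h <- nd_conv2d(tape, h, p[[paste0("conv", l, "_w")]],
                   p[[paste0("conv", l, "_b")]], stride = 1L, pad = pad)
    h <- nd_bn_gelu(tape, h, p[[paste0("bn", l, "_gamma")]],
                    p[[paste0("bn", l, "_beta")]],
                    enc$states[[paste0("bn", l)]], training = training)
    pyr[[l]] <- h
  }
  pyr
}

#' Reflection-pad an image to dimensions divisible by a multiple
#'
#' @param image H x W matrix.
#' @param multiple the required divisor (2^(L-1) for an L-level encoder).
#' @return list with `image` (padded) and the original `height`/`width`.
#' @export
pad_to_multiple <- function(image, multiple) {
  H <- nrow(image); W <- ncol(image)
  Hp <- as.integer(multiple * ceiling(H / multiple))
  Wp <- as.integer(multiple * ceiling(W / multiple))
  if (Hp != H) {
    extra <- rev(seq_len(Hp - H)) + (H - (Hp - H))
    image <- image[c(seq_len(H), extra), , drop = FALSE]
  }
  if (Wp != W) {
    extra <- rev(seq_len(Wp - W)) + (W - (Wp - W))
    image <- image[, c(seq_len(W), extra), drop = FALSE]
  }
  list(image = image, height = H, width = W)
}

#' Extract the multi-scale feature pyramid of one image
#'
#' Deterministic evaluation-mode forward pass: level l has spatial size
#' `H / 2^(l-1)` x `W / 2^(l-1)` (after reflection padding to divisibility)
#' and `base_channels * growth^(l-1)` channels.
#'
#' @param encoder an encoder from [build_encoder()].
#' @param image H x W matrix.
#' @return list of L arrays `(H_l, W_l, C_l)`.
#' @export
extract_pyramid <- function(encoder, image) {
  stopifnot(inherits(encoder, "mfafn_encoder"))
  m <- 2L^(encoder$config$levels - 1L)
  padded <- pad_to_multiple(as.matrix(image), m)
  x <- ad_const(array(padded$image, c(dim(padded$image), 1L, 1L)))
  pyr <- encoder_forward(encoder, x, tape = NULL, training = FALSE)
  lapply(pyr, function(nd) {
    d <- dim(nd$value)
    array(nd$value, d[1:3])
  })
}

#' Count trainable parameters
#'
#' @param x an encoder or model object with a `params` list.
#' @return total number of scalar parameters.
#' @export
n_params <- function(x) {
  sum(vapply(x$params, function(p) length(p$value), numeric(1)))
}
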