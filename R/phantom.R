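#' Phantom generation configuration
#'
#' Describes a registered multi-pseudo-modality phantom: a shared ground-truth
#' structure (a branching vessel-like tree or a union of polyp-like blobs)
#' rendered once per modality with per-modality gain/bias offsets and additive
#' Gaussian noise. With `complementary = TRUE` (default) modality 1 renders the
#' thin structure at full contrast while later modalities render a blurred,
#' gamma-shifted view plus a smooth background texture, so fusion has
#' complementary information to recover. All randomness is derived from `seed`
#' through a counter-based splitting scheme, so generation is bit-reproducible
#' and adding samples never perturbs earlier ones.
#'
#' @param height,width image size in pixels (at least 16).
#' @param n_modalities number of registered pseudo-modality renderings, N >= 1.
#' @param structure `"branching"` (random binary tree of anti-aliased line
#'   segments) or `"blob"` (union of random anti-aliased ellipses).
#' @param contrast peak foreground intensity, in (0, 1].
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param modality_offsets list of `c(gain, bias)` pairs, one per modality.
#' @param complementary render later modalities as blurred/gamma-shifted
#'   complementary views (see Details). Set `FALSE` for identical renderings.
#' @param blob_spec optional list of ellipses `list(c(cx, cy, a, b, theta))`
#'   in pixel units overriding random blob placement (used for analytic
#'   area checks).
#' @param seed integer seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height = 32L, width = 32L, n_modalities = 2L,
                           structure = c("branching", "blob"),
                           contrast = 0.8, noise_sigma = 0.05,
                           modality_offsets = NULL, complementary = TRUE,
                           blob_spec = NULL, seed = 1L) {
  structure <- match.arg(structure)
  height <- as.integer(height); width <- as.integer(width)
  n_modalities <- as.integer(n_modalities)
  if (is.na(height) || is.na(width) || height < 16L || width < 16L) {
    stop("phantom_config: height and width must be >= 16", call. = FALSE)
  }
  if (is.na(n_modalities) || n_modalities < 1L) {
    stop("phantom_config: n_modalities must be >= 1", call. = FALSE)
  }
  if (!is.numeric(contrast) || contrast <= 0 || contrast > 1) {
    stop("phantom_config: contrast must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("phantom_config: noise_sigma must be >= 0", call. = FALSE)
  }
  if (is.null(modality_offsets)) {
    modality_offsets <- lapply(seq_len(n_modalities), function(i) {
      if (i == 1L) c(1, 0) else c(0.85, 0.08 * (i - 1L))
    })
  }
  if (length(modality_offsets) != n_modalities) {
    stop("phantom_config: need one (gain, bias) offset per modality", call. = FALSE)
  }
  structure(list(height = height, width = width, n_modalities = n_modalities,
                 structure = structure, contrast = contrast,
                 noise_sigma = noise_sigma, modality_offsets = modality_offsets,
                 complementary = isTRUE(complementary), blob_spec = blob_spec,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# counter-based seed splitting: a derived stream seed for (seed, index)
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# distance from grid points to a segment (x1,y1)-(x2,y2); x = column, y = row
.seg_dist <- function(xg, yg, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 < 1e-12) return(sqrt((xg - x1)^2 + (yg - y1)^2))
  t <- ((xg - x1) * dx + (yg - y1) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((xg - x1 - t * dx)^2 + (yg - y1 - t * dy)^2)
}

# anti-aliased intensity in [0,1] from a signed distance beyond radius
.soft_edge <- function(dist, radius, aa = 0.8) {
  pmin(pmax((radius + aa / 2 - dist) / aa, 0), 1)
}

# random binary tree of line segments; returns intensity field in [0,1]
.draw_branching <- function(H, W) {
  xg <- matrix(rep(seq_len(W), each = H), H, W)
  yg <- matrix(rep(seq_len(H), times = W), H, W)
  img <- matrix(0, H, W)
  scale <- min(H, W)
  grow <- function(x, y, angle, len, width, depth) {
    x2 <- x + len * cos(angle)
    y2 <- y + len * sin(angle)
    d <- .seg_dist(xg, yg, x, y, x2, y2)
    img <<- pmax(img, .soft_edge(d, width))
    if (depth <= 0L || width < 0.35) return(invisible(NULL))
    nb <- if (stats::runif(1) < 0.7) 2L else 1L
    for (k in seq_len(nb)) {
      da <- stats::runif(1, 0.25, 0.7) * (if (k == 1L) 1 else -1) +
        stats::rnorm(1, 0, 0.1)
      grow(x2, y2, angle + da, len * stats::runif(1, 0.6, 0.85),
           width * stats::runif(1, 0.6, 0.8), depth - 1L)
    }
    invisible(NULL)
  }
  x0 <- stats::runif(1, 0.3 * W, 0.7 * W)
  grow(x0, 1, pi / 2 + stats::rnorm(1, 0, 0.2),
       stats::runif(1, 0.35, 0.5) * scale, 0.06 * scale, 3L)
  img
}

# union of random ellipses; blob_spec overrides placement when given
.draw_blobs <- function(H, W, blob_spec = NULL) {
  xg <- matrix(rep(seq_len(W), each = H), H, W)
  yg <- matrix(rep(seq_len(H), times = W), H, W)
  img <- matrix(0, H, W)
  if (is.null(blob_spec)) {
    n <- sample(1:3, 1L)
    blob_spec <- lapply(seq_len(n), function(i) {
      c(stats::runif(1, 0.3 * W, 0.7 * W), stats::runif(1, 0.3 * H, 0.7 * H),
        stats::runif(1, 0.12, 0.28) * W, stats::runif(1, 0.12, 0.28) * H,
        stats::runif(1, 0, pi))
    })
  }
  for (e in blob_spec) {
    cx <- e[1L]; cy <- e[2L]; a <- e[3L]; b <- e[4L]; th <- e[5L]
    u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
    v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
    # approximate signed distance from the ellipse boundary
    r <- sqrt((u / a)^2 + (v / b)^2)
    d <- (r - 1) * min(a, b)
    img <- pmax(img, pmin(pmax(0.5 - d / 0.8, 0), 1))
  }
  img
}

# smooth low-frequency background texture in [0, amp]
.background_texture <- function(H, W, amp = 0.15) {
  coarse <- matrix(stats::runif(64, 0, 1), 8, 8)
  ri <- pmin(pmax(ceiling(seq_len(H) / H * 8), 1L), 8L)
  ci <- pmin(pmax(ceiling(seq_len(W) / W * 8), 1L), 8L)
  up <- coarse[ri, ci, drop = FALSE]
  amp * .gauss_blur(up, sigma = max(H, W) / 16)
}

# separable Gaussian blur with replicate borders (shared helper)
.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  H <- nrow(img); W <- ncol(img)
  xp <- img[pad_idx(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_along(k)) out <- out + k[j] * xp[(j - 1L) + seq_len(H), , drop = FALSE]
  xp <- out[, pad_idx(W), drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_along(k)) out <- out + k[j] * xp[, (j - 1L) + seq_len(W), drop = FALSE]
  out
}

#' Generate a registered multi-pseudo-modality phantom
#'
#' Renders one ground-truth structure into `n_modalities` registered images.
#' Modality `i` is `clip(gain_i * S_i + bias_i + eps)` with
#' `eps ~ N(0, noise_sigma^2)`, where `S_1` is the structure intensity scaled
#' by `contrast` and, under complementary rendering, `S_i` for `i > 1` is a
#' blurred, gamma-lifted view of the structure plus background texture.
#'
#' @param config a [phantom_config()].
#' @return list with `images` (list of H x W matrices in \[0,1\]) and `mask`
#'   (H x W binary matrix).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$height; W <- config$width
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(config$seed, 0L))
  struct <- if (config$structure == "branching") {
    .draw_branching(H, W)
  } else {
    .draw_blobs(H, W, config$blob_spec)
  }
  mask <- (struct >= 0.5) * 1
  images <- vector("list", config$n_modalities)
  for (i in seq_len(config$n_modalities)) {
    set.seed(derive_seed(config$seed, i))
    si <- struct * config$contrast
    if (config$complementary && i > 1L) {
      si <- .gauss_blur(struct, sigma = 1.2)^0.7 * config$contrast +
        .background_texture(H, W)
    }
    off <- config$modality_offsets[[i]]
    img <- off[1L] * si + off[2L]
    if (config$noise_sigma > 0) {
      img <- img + stats::rnorm(H * W, 0, config$noise_sigma)
    }
    images[[i]] <- matrix(pmin(pmax(img, 0), 1), H, W)
  }
  list(images = images, mask = mask)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Write a phantom dataset to disk
#'
#' Generates `n_train + n_val` phantoms (per-sample seeds derived from `seed`
#' by counter splitting), writes images and masks as 8-bit PNG and a JSON
#' manifest listing paths, split labels and per-sample seeds. Re-running with
#' identical arguments reproduces the files bit-identically.
#'
#' @param n_train,n_val split sizes (each >= 1).
#' @param config a [phantom_config()]; its `seed` field is ignored in favour
#'   of the per-sample derived seeds.
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
make_dataset <- function(n_train, n_val, config, out_dir, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_train < 1L || n_val < 1L) {
    stop("make_dataset: n_train and n_val must be >= 1", call. = FALSE)
  }
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("make_dataset: cannot create output directory ", out_dir, call. = FALSE)
  }
  n <- n_train + n_val
  entries <- vector("list", n)
  for (s in seq_len(n)) {
    cfg_s <- config
    cfg_s$seed <- derive_seed(seed, s)
    ph <- generate_phantom(cfg_s)
    base <- sprintf("sample_%04d", s)
    img_paths <- character(config$n_modalities)
    for (i in seq_len(config$n_modalities)) {
      img_paths[i] <- file.path(out_dir, sprintf("%s_mod%d.png", base, i))
      write_image_png(ph$images[[i]], img_paths[i])
    }
    mask_path <- file.path(out_dir, sprintf("%s_mask.png", base))
    write_mask_png(ph$mask, mask_path)
    entries[[s]] <- list(id = base,
                         split = if (s <= n_train) "train" else "val",
                         seed = cfg_s$seed,
                         images = as.list(img_paths),
                         mask = mask_path)
  }
  manifest <- list(schema = "mfafuse-manifest-1", master_seed = as.integer(seed),
                   height = config$height, width = config$width,
                   n_modalities = config$n_modalities,
                   structure = config$structure,
                   samples = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a dataset manifest and its samples into memory
#'
#' @param manifest_path path to `manifest.json` written by [make_dataset()].
#' @return list with `manifest` and `samples` (each sample: list of image
#'   matrices plus mask matrix and split label).
#' @export
load_dataset <- function(manifest_path) {
  manifest <- jsonlite::read_json(manifest_path)
  samples <- lapply(manifest$samples, function(e) {
    list(id = e$id, split = e$split,
         images = lapply(e$images, read_image_png),
         mask = read_mask_png(e$mask))
  })
  list(manifest = manifest, samples = samples)
}
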