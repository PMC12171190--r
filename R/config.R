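# Run configuration: nested schema with defaults, strict validation
# (unknown keys rejected with their path), YAML/JSON parsing, and provenance.

config_defaults <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    preprocess = list(method = "zscore", calibrate = TRUE),
    encoder = list(preset = "tiny", levels = 4L, base_channels = 8L,
                   kernel_size = 3L, channel_growth = 2),
    attention = list(residual = TRUE),
    dfrs = list(enabled = TRUE, saliency_weighting = TRUE,
                context_refinement = TRUE),
    fusion = list(method = "mfafn", laplacian_levels = 4L),
    train = list(lr = 1e-4, warmup = 5L, early_stop_patience = 10L,
                 batch_size = 8L, max_epochs = 40L,
                 loss_weights = c(0.5, 0.5), threshold = 0.5),
    eval = list(bins = 256L, threshold = 0.5),
    simulate = list(height = 32L, width = 32L, n_modalities = 2L,
                    structure = "blob", contrast = 0.8, noise_sigma = 0.05,
                    complementary = TRUE, n_train = 8L, n_val = 2L)
  )
}

# merge user values over defaults, rejecting unknown keys; path for messages
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop("config: expected a section at ", path, call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("config: unknown key ", paste0(sub("^\\.", "", paste0(path, ".", unknown[1L]))),
         call. = FALSE)
  }
  for (nm in names(user)) {
    key_path <- paste0(path, ".", nm)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], key_path)
    } else {
      v <- user[[nm]]
      if (is.list(v)) v <- unlist(v)
      defaults[[nm]] <- v
    }
  }
  defaults
}

.cfg_fail <- function(key, msg) {
  stop("config: ", key, " ", msg, call. = FALSE)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!preprocess$method %in% c("zscore", "minmax")) {
      .cfg_fail("preprocess.method", "must be 'zscore' or 'minmax'")
    }
    if (encoder$levels < 1L) .cfg_fail("encoder.levels", "must be >= 1")
    if (encoder$base_channels < 1L) .cfg_fail("encoder.base_channels", "must be >= 1")
    if (encoder$kernel_size %% 2L == 0L) .cfg_fail("encoder.kernel_size", "must be odd")
    if (!fusion$method %in% c("mfafn", "laplacian")) {
      .cfg_fail("fusion.method", "must be 'mfafn' or 'laplacian'")
    }
    if (train$warmup >= train$max_epochs) {
      .cfg_fail("train.warmup", "must be < train.max_epochs")
    }
    if (train$early_stop_patience < 1L) {
      .cfg_fail("train.early_stop_patience", "must be >= 1")
    }
    if (length(train$loss_weights) != 2L) {
      .cfg_fail("train.loss_weights", "must be two numbers (dice, ce)")
    }
    if (eval$bins < 2L) .cfg_fail("eval.bins", "must be >= 2")
    if (!simulate$structure %in% c("branching", "blob")) {
      .cfg_fail("simulate.structure", "must be 'branching' or 'blob'")
    }
    if (simulate$height < 16L || simulate$width < 16L) {
      .cfg_fail("simulate.height/width", "must be >= 16")
    }
  })
  invisible(cfg)
}

#' Parse and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, fills defaults for omitted keys,
#' rejects unknown keys (naming the offending path) and validates every
#' constraint. Re-parsing a resolved configuration is the identity.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`), or `NULL` for
#'   all defaults.
#' @return resolved configuration of class `run_config`.
#' @export
parse_config <- function(path = NULL) {
  user <- if (is.null(path)) {
    list()
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("config: the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- merge_config(config_defaults(), user)
  cfg$seed <- as.integer(cfg$seed)
  for (k in c("levels", "base_channels", "kernel_size")) {
    cfg$encoder[[k]] <- as.integer(cfg$encoder[[k]])
  }
  for (k in c("warmup", "early_stop_patience", "batch_size", "max_epochs")) {
    cfg$train[[k]] <- as.integer(cfg$train[[k]])
  }
  for (k in c("height", "width", "n_modalities", "n_train", "n_val")) {
    cfg$simulate[[k]] <- as.integer(cfg$simulate[[k]])
  }
  cfg$eval$bins <- as.integer(cfg$eval$bins)
  validate_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

# write the fully resolved configuration + provenance next to run outputs
write_provenance <- function(cfg, out_dir, seed = cfg$seed) {
  rec <- list(package = "mfafuse",
              version = as.character(utils::packageVersion("mfafuse")),
              seed = as.integer(seed),
              config = unclass(cfg))
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}

# sidecar provenance record for single-file outputs
write_provenance_sidecar <- function(cfg, out_path, seed = cfg$seed) {
  rec <- list(package = "mfafuse",
              version = as.character(utils::packageVersion("mfafuse")),
              seed = as.integer(seed),
              output = basename(out_path),
              config = unclass(cfg))
  jsonlite::write_json(rec, paste0(out_path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}

# helpers mapping a run_config onto module constructors
config_to_encoder <- function(cfg) {
  if (identical(cfg$encoder$preset, "paper")) {
    encoder_config(levels = 4L, base_channels = 64L, preset = "paper")
  } else {
    encoder_config(levels = cfg$encoder$levels,
                   base_channels = cfg$encoder$base_channels,
                   kernel_size = cfg$encoder$kernel_size,
                   channel_growth = cfg$encoder$channel_growth)
  }
}

config_to_model <- function(cfg, n_modalities, seed = cfg$seed) {
  mfafn_build(n_modalities, config_to_encoder(cfg),
              attention = if (isTRUE(cfg$attention$residual)) "residual" else "plain",
              weight_mode = if (isTRUE(cfg$dfrs$enabled) &&
                                isTRUE(cfg$dfrs$saliency_weighting)) "saliency" else "learned",
              context_refinement = isTRUE(cfg$dfrs$enabled) &&
                isTRUE(cfg$dfrs$context_refinement),
              seed = seed)
}

config_to_train <- function(cfg, seed = cfg$seed) {
  train_config(lr = cfg$train$lr, warmup = cfg$train$warmup,
               early_stop_patience = cfg$train$early_stop_patience,
               batch_size = cfg$train$batch_size,
               max_epochs = cfg$train$max_epochs,
               loss_weights = cfg$train$loss_weights,
               threshold = cfg$train$threshold, seed = seed)
}

config_to_phantom <- function(cfg, seed = cfg$seed) {
  phantom_config(height = cfg$simulate$height, width = cfg$simulate$width,
                 n_modalities = cfg$simulate$n_modalities,
                 structure = cfg$simulate$structure,
                 contrast = cfg$simulate$contrast,
                 noise_sigma = cfg$simulate$noise_sigma,
                 complementary = cfg$simulate$complementary,
                 seed = seed)
}
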