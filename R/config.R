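# Run configuration: a YAML document mapping onto the spec constructors,
# with full defaults for every unspecified key and strict rejection of
# unknown keys.

config_defaults <- function() {
  list(
    scale = 4L,
    seed = 0L,
    generator = list(widths = c(32L, 64L, 128L, 256L), stem_units = 4L,
                     stem_width = 64L, stage_module_counts = c(1L, 4L, 3L),
                     blocks_per_module = 4L, deconv_kernels = c(5L, 7L, 11L),
                     aggregation = "deconv", trunk = "multires",
                     plain_blocks = 8L),
    discriminator = list(channels = c(64L, 64L, 128L, 128L, 256L, 256L,
                                      512L, 512L),
                         strides = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
                         dense_width = 1024L, use_batchnorm = TRUE,
                         activation = "relu"),
    loss_weights = list(a1 = 1, a2 = 0.001),
    training = list(initial_lr = 1e-4, halving_interval = 50L,
                    total_epochs = 200L, batch_size = 16L, hr_patch = 96L,
                    seed = 0L, mode = "gan", betas = c(0.9, 0.999),
                    grad_clip = NULL)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration key '%s' must be a mapping", full))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Default run configuration
#'
#' The fully resolved default configuration: scale 4, the reference
#' generator (widths 32/64/128/256) and discriminator, loss weights
#' `a1 = 1`, `a2 = 0.001`, and the 200-epoch training schedule.
#'
#' @return A `run_config` list with constructed spec objects.
#' @export
default_config <- function() build_run_config(config_defaults())

build_run_config <- function(raw) {
  r <- tryCatch(scale_factor(raw$scale),
                error = function(e) stop("config key 'scale': ",
                                         conditionMessage(e), call. = FALSE))
  if (raw$seed < 0) stop("config key 'seed': seed must be >= 0")
  wrap <- function(section, f, args) {
    tryCatch(do.call(f, args),
             error = function(e) stop(sprintf("config section '%s': %s",
                                              section, conditionMessage(e)),
                                      call. = FALSE))
  }
  tr <- raw$training
  tr$grad_clip <- raw$training$grad_clip
  structure(list(
    scale = r,
    seed = as.integer(raw$seed),
    generator = wrap("generator", generator_spec, raw$generator),
    discriminator = wrap("discriminator", discriminator_spec,
                         raw$discriminator),
    loss_weights = wrap("loss_weights", loss_weights, raw$loss_weights),
    training = wrap("training", training_config, tr)
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unspecified keys take their defaults (see [default_config()]); unknown
#' keys and invalid values are rejected with the offending key named.
#'
#' @param path Path to a YAML file; `NULL` returns the defaults.
#' @return A `run_config` list: `scale`, `seed`, `generator`,
#'   `discriminator`, `loss_weights`, `training`.
#' @export
load_config <- function(path = NULL) {
  raw <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    raw <- merge_config(raw, user)
  }
  build_run_config(raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config: scale %d, %s trunk widths %s, mode %s, %d epochs>\n",
              x$scale, x$generator$trunk,
              paste(x$generator$widths, collapse = "/"),
              x$training$mode, x$training$total_epochs))
  invisible(x)
}
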