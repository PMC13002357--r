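#' Experiment configuration
#'
#' Bundles the per-stage configurations plus harness-level settings into one
#' object consumed by the sweep functions and the CLI. All randomness in a
#' run derives from `seed` via [stage_seed()].
#'
#' @param preprocess a [preprocess_config()].
#' @param sampling a [sampling_config()].
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param direction_mode default deformation direction for label noise.
#' @param threshold binarization threshold.
#' @param augment quadruple training patches by rotation.
#' @param seed run seed.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(preprocess = preprocess_config(),
                              sampling = sampling_config(),
                              model = model_config(),
                              train = train_config(),
                              direction_mode = "zoom_in",
                              threshold = 0.5, augment = TRUE, seed = 1L) {
  abort_if(threshold < 0 || threshold > 1, "threshold must lie in [0, 1]")
  structure(list(preprocess = preprocess, sampling = sampling, model = model,
                 train = train, direction_mode = direction_mode,
                 threshold = threshold, augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The file mirrors the [experiment_config()] structure: top-level keys
#' `preprocess`, `sampling`, `model`, `train` hold the fields of the
#' corresponding config constructors; `direction_mode`, `threshold`,
#' `augment` and `seed` are top-level. Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) yaml::read_yaml(path) else list()
  raw <- modifyList(raw, overrides)
  build <- function(ctor, key) do.call(ctor, raw[[key]] %||% list())
  experiment_config(
    preprocess = build(preprocess_config, "preprocess"),
    sampling = build(sampling_config, "sampling"),
    model = build(model_config, "model"),
    train = build(train_config, "train"),
    direction_mode = raw$direction_mode %||% "zoom_in",
    threshold = raw$threshold %||% 0.5,
    augment = raw$augment %||% TRUE,
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
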