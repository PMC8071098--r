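#' Default run configuration
#'
#' One declarative structure holding every experiment knob with its
#' documented default: epoch length (s), sub-band scheme, Welch parameters,
#' classifier snapshot and seed, cross-validation fold count, synthetic
#' generator settings, quantizer specs, streaming buffer capacity and
#' pacing flag. [load_config()] merges a YAML file over these defaults.
#'
#' @return Named list, classed `run_config`.
#' @export
default_config <- function() {
  structure(list(
    epoch_length_s = 64,
    fs = 256,
    bands = list(
      delta = c(1, 3.5), theta = c(4, 7.5), alpha = c(8, 12),
      sigma = c(13, 16), beta = c(16.5, 25), gamma = c(30, 35)
    ),
    welch = list(segment_s = 4, overlap = 0.5),
    eps = 1e-12,
    baseline_n_first = 5,
    classifier = classifier_defaults(),
    seed = 42L,
    cv_folds = 10,
    synth = list(
      epochs_per_class = 25,
      subjects_per_group = 3
    ),
    dac = list(bits = 12, v_min = 0, v_max = 3.3),
    adc = list(bits = 10, v_min = 0, v_max = 3.3),
    headroom = 0.05,
    buffer_capacity = 16,
    pacing = FALSE
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and merges it (recursively, by name) over
#' [default_config()]; fields absent from the file keep their defaults.
#' The merged configuration is validated.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  if (!cfg$epoch_length_s %in% c(16, 32, 64)) {
    stop_validation("`epoch_length_s` must be one of 16, 32, 64")
  }
  sub_band_scheme(cfg$bands) # validates edges
  if (cfg$fs <= 2 * max(unlist(cfg$bands))) {
    stop_validation("`fs` must exceed twice the highest band edge")
  }
  if (cfg$cv_folds < 2) stop_validation("`cv_folds` must be >= 2")
  if (cfg$buffer_capacity < 1) stop_validation("`buffer_capacity` must be >= 1")
  quantizer_spec(cfg$dac$bits, cfg$dac$v_min, cfg$dac$v_max)
  quantizer_spec(cfg$adc$bits, cfg$adc$v_min, cfg$adc$v_max)
  invisible(cfg)
}

#' Persist a configuration snapshot next to an output
#'
#' @param cfg A `run_config`.
#' @param path YAML output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_scheme <- function(cfg) sub_band_scheme(cfg$bands)
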