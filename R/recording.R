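#' Class labels used throughout the package
#'
#' The four epoch classes, in the fixed (alphabetical) encoding used for all
#' confusion matrices and model outputs: sham vs. mTBI condition crossed with
#' wake vs. sleep vigilance state.
#'
#' @return Character vector of the four class labels.
#' @export
class_levels <- function() {
  c("SHAM_SLEEP", "SHAM_WAKE", "TBI_SLEEP", "TBI_WAKE")
}

#' Construct a single-channel EEG recording
#'
#' A uniformly sampled single-channel signal with its sampling rate and
#' channel metadata. Amplitudes are kept in the units of the source (EDF
#' physical units or arbitrary units for synthetic signals).
#'
#' @param samples Numeric vector of signal amplitudes; must be non-empty and
#'   finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_name Channel label stored with the recording.
#' @param start_time Optional start timestamp (`POSIXct`) or `NULL`.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 10 * (0:255) / 256), fs = 256)
#' rec
#' @export
eeg_recording <- function(samples, fs, channel_name = "EEG", start_time = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop_validation("`samples` must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) {
    stop_validation("`samples` must be finite (no NA/NaN/Inf)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_validation("`fs` must be a positive scalar (Hz)")
  }
  structure(
    list(
      samples = as.numeric(samples),
      fs = as.numeric(fs),
      channel_name = as.character(channel_name),
      start_time = start_time
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> channel '%s': %d samples @ %g Hz (%.1f s)\n",
    x$channel_name, length(x$samples), x$fs, length(x$samples) / x$fs
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param recording An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  length(recording$samples) / recording$fs
}

new_epoch <- function(samples, fs, length_s, index, label = NA_character_) {
  structure(
    list(
      samples = samples, fs = fs, length_s = length_s,
      index = index, label = label
    ),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf(
    "<eeg_epoch> #%d: %g s @ %g Hz, label %s\n",
    x$index, x$length_s, x$fs,
    if (is.na(x$label)) "<none>" else x$label
  ))
  invisible(x)
}

#' Segment a recording into non-overlapping fixed-length epochs
#'
#' Cuts the recording into consecutive windows of `length_s` seconds, the
#' unit of classification. A trailing partial window is dropped, never
#' padded, so a 6400 s recording at 64 s epochs yields exactly 100 epochs
#' and a 63 s recording yields none.
#'
#' Labels may be supplied either on the epoch grid (one label per epoch) or
#' on a finer grid via `label_interval_s` (e.g. 4 s manual sleep scores). In
#' the finer case each epoch receives the majority label among its
#' constituent scores, with ties broken toward wake (any label containing
#' `"WAKE"` wins a tie).
#'
#' @param recording An `eeg_recording`.
#' @param length_s Epoch length in seconds; `length_s * fs` must be a whole
#'   number of samples. Conventional values are 16, 32 and 64.
#' @param labels Optional character vector of labels, one per epoch (or per
#'   `label_interval_s` block when that is given).
#' @param label_interval_s Granularity of `labels` in seconds; defaults to
#'   `length_s` (labels already on the epoch grid). Must divide `length_s`.
#' @return List of `eeg_epoch` objects, ordered and non-overlapping.
#' @examples
#' rec <- eeg_recording(rnorm(256 * 128), fs = 256)
#' length(segment_epochs(rec, 64)) # 2
#' @export
segment_epochs <- function(recording, length_s, labels = NULL,
                           label_interval_s = length_s) {
  stopifnot(inherits(recording, "eeg_recording"))
  n_per <- length_s * recording$fs
  if (abs(n_per - round(n_per)) > 1e-9) {
    stop_validation("`length_s * fs` must be an integer number of samples")
  }
  n_per <- as.integer(round(n_per))
  n_epochs <- length(recording$samples) %/% n_per
  if (!is.null(labels)) {
    labels <- collapse_labels(labels, length_s, label_interval_s)
    if (length(labels) < n_epochs) {
      stop_validation(sprintf(
        "label sequence covers %d epochs but recording has %d",
        length(labels), n_epochs
      ))
    }
  }
  lapply(seq_len(n_epochs), function(i) {
    idx <- ((i - 1L) * n_per + 1L):(i * n_per)
    new_epoch(
      samples = recording$samples[idx],
      fs = recording$fs,
      length_s = length_s,
      index = i - 1L,
      label = if (is.null(labels)) NA_character_ else labels[i]
    )
  })
}

# Majority vote of fine-grained scores within each analysis epoch; ties go
# to the wake label (labels are compared case-insensitively for "WAKE").
collapse_labels <- function(labels, length_s, label_interval_s) {
  if (label_interval_s == length_s) {
    return(as.character(labels))
  }
  ratio <- length_s / label_interval_s
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop_validation("`label_interval_s` must divide `length_s`")
  }
  ratio <- as.integer(round(ratio))
  n_out <- length(labels) %/% ratio
  vapply(seq_len(n_out), function(i) {
    block <- labels[((i - 1L) * ratio + 1L):(i * ratio)]
    tab <- table(block)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1L) {
      wake <- winners[grepl("WAKE", toupper(winners))]
      if (length(wake) > 0L) winners <- wake
    }
    winners[1L]
  }, character(1))
}

#' Extract labels from a list of epochs
#'
#' @param epochs List of `eeg_epoch` objects.
#' @return Character vector of labels (possibly `NA`).
#' @export
epoch_labels <- function(epochs) {
  vapply(epochs, function(e) e$label, character(1))
}

# --- classed error helpers (used for CLI exit-code mapping) ----------------

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("eegpipe_validation_error", "error")))
}

stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("eegpipe_io_error", "error")))
}

stop_usage <- function(msg) {
  stop(errorCondition(msg, class = c("eegpipe_usage_error", "error")))
}
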