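#' Playback sample source
#'
#' Wraps a recording as a stream source for the capture/processing engine:
#' samples are replayed in order at the recording's nominal rate (virtual
#' time; optionally paced to the wall clock by the engine).
#'
#' @param recording An [eeg_recording()].
#' @return Object of class `sample_source`.
#' @export
playback_source <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  structure(
    list(kind = "playback", recording = recording, fs = recording$fs),
    class = "sample_source"
  )
}

#' Emulated hardware-loop sample source
#'
#' Replays a recording through the emulated DAC-to-ADC chain before
#' capture, so streamed epochs carry the quantization error of the
#' playback loop — the software analogue of generating the signal on a
#' DAC and re-digitizing it with an ADC.
#'
#' @param recording An [eeg_recording()].
#' @param dac_spec,adc_spec [quantizer_spec()]s for the two converters.
#' @param headroom Fraction of the voltage span left unused at each end
#'   (default 0.05).
#' @return Object of class `sample_source`.
#' @export
hardware_loop_source <- function(recording, dac_spec = quantizer_spec(12),
                                 adc_spec = quantizer_spec(10),
                                 headroom = 0.05) {
  cmp <- verify_playback(recording, dac_spec, adc_spec, headroom = headroom)
  looped <- eeg_recording(cmp$observed, fs = recording$fs,
                          channel_name = recording$channel_name,
                          start_time = recording$start_time)
  structure(
    list(kind = "hardware_loop", recording = looped, fs = looped$fs,
         comparison = cmp),
    class = "sample_source"
  )
}

#' @export
print.sample_source <- function(x, ...) {
  cat(sprintf("<sample_source> %s: %d samples @ %g Hz\n", x$kind,
              length(x$recording$samples), x$fs))
  invisible(x)
}

#' Run the capture-while-processing streaming engine
#'
#' Emulates the real-time acquisition/classification loop: a capture path
#' accumulates source samples into epoch buckets; each completed epoch is
#' placed on a bounded first-in-first-out buffer; an independent processing
#' path drains the buffer, running feature extraction and classification on
#' each epoch exactly once. Capture and processing progress independently
#' on a shared virtual timeline (epoch `i` completes capture at
#' `(i+1) * epoch_length_s`; the processor starts an epoch as soon as it is
#' both free and the epoch is buffered), which makes every run bit-
#' reproducible while preserving the producer/consumer contract: no epoch
#' is ever lost as long as mean per-epoch processing time is below the
#' epoch collection time.
#'
#' If the buffer is full when an epoch completes, the oldest buffered epoch
#' is dropped and counted — overflow is never silent. Per-epoch processing
#' time is measured around preprocessing + feature extraction +
#' classification only. By default the virtual service time of an epoch is
#' its measured processing time (accelerated playback: no wall-clock
#' sleeping); `pacing = TRUE` additionally sleeps capture to the wall
#' clock, and `simulated_proc_time_s` overrides the service time to stress
#' the overflow policy.
#'
#' @param source A `sample_source` or an [eeg_recording()] (implies
#'   playback).
#' @param epoch_length_s Epoch length in seconds.
#' @param model Trained [train_classifier()] model.
#' @param baseline [compute_baseline()] result used for dB normalization.
#' @param scheme,segment_s,overlap Spectral parameters.
#' @param max_epochs Cap on the number of epochs captured (default all
#'   full epochs in the source).
#' @param buffer_capacity Bounded buffer size in epochs (default 16).
#' @param pacing Sleep capture to the wall clock (default `FALSE`,
#'   accelerated playback).
#' @param simulated_proc_time_s Override the virtual per-epoch service
#'   time in seconds (testing hook for the overflow policy); `NULL` uses
#'   measured processing time.
#' @param keep_epochs Keep the processed epochs' samples in the result
#'   (for integrity checks).
#' @return Object of class `stream_stats`: counts of generated / captured /
#'   processed / lost epochs, `epoch_loss_fraction`, per-epoch processing
#'   times, the predicted-label histogram, a per-epoch prediction table,
#'   and an `error` field (`NULL`, or the message if the source failed
#'   mid-stream, in which case stats up to the failure are returned).
#' @export
run_stream <- function(source, epoch_length_s, model, baseline,
                       scheme = sub_band_scheme(), segment_s = 4,
                       overlap = 0.5, max_epochs = Inf,
                       buffer_capacity = 16, pacing = FALSE,
                       simulated_proc_time_s = NULL, keep_epochs = FALSE) {
  if (inherits(source, "eeg_recording")) source <- playback_source(source)
  stopifnot(inherits(source, "sample_source"))
  if (buffer_capacity < 1) stop_validation("`buffer_capacity` must be >= 1")
  rec <- source$recording
  n_per <- epoch_length_s * rec$fs
  if (abs(n_per - round(n_per)) > 1e-9) {
    stop_validation("`epoch_length_s * rate` must be an integer sample count")
  }
  n_per <- as.integer(round(n_per))
  n_total <- min(length(rec$samples) %/% n_per, max_epochs)

  buffer <- list()       # FIFO of list(index, avail_t, samples)
  proc_free_at <- 0
  processed_idx <- integer(0)
  pred_labels <- character(0)
  proc_times <- numeric(0)
  lost <- 0L
  captured <- 0L
  kept <- if (keep_epochs) list() else NULL
  err <- NULL

  process_one <- function(item) {
    t0 <- proc.time()[["elapsed"]]
    ep <- new_epoch(item$samples, rec$fs, epoch_length_s, item$index)
    feats <- extract_features(ep, baseline, scheme,
                              segment_s = segment_s, overlap = overlap)
    lab <- predict(model, matrix(feats, nrow = 1,
                                 dimnames = list(NULL, names(feats))))
    elapsed <- proc.time()[["elapsed"]] - t0
    list(label = lab, elapsed = elapsed)
  }

  consume <- function(item) {
    res <- process_one(item)
    processed_idx <<- c(processed_idx, item$index)
    pred_labels <<- c(pred_labels, res$label)
    proc_times <<- c(proc_times, res$elapsed)
    if (keep_epochs) kept[[length(kept) + 1L]] <<- item$samples
    res$elapsed
  }

  service_time <- function(measured) {
    if (is.null(simulated_proc_time_s)) measured else simulated_proc_time_s
  }

  i <- 0L
  while (i < n_total && is.null(err)) {
    arrive_t <- (i + 1) * epoch_length_s
    # processing path: drain every epoch the processor can start before the
    # next capture completes
    while (length(buffer) > 0) {
      head <- buffer[[1]]
      start_t <- max(proc_free_at, head$avail_t)
      if (start_t >= arrive_t) break
      buffer <- buffer[-1]
      measured <- consume(head)
      proc_free_at <- start_t + service_time(measured)
    }
    # capture path: accumulate the next epoch bucket
    item <- tryCatch({
      samples <- rec$samples[(i * n_per + 1L):((i + 1L) * n_per)]
      if (pacing) Sys.sleep(epoch_length_s)
      list(index = i, avail_t = arrive_t, samples = samples)
    }, error = function(e) e)
    if (inherits(item, "error")) {
      err <- conditionMessage(item)
      break
    }
    captured <- captured + 1L
    if (length(buffer) >= buffer_capacity) {
      buffer <- buffer[-1] # drop-oldest, counted
      lost <- lost + 1L
    }
    buffer[[length(buffer) + 1L]] <- item
    i <- i + 1L
  }
  # source exhausted: the processor catches up on the backlog
  while (length(buffer) > 0) {
    head <- buffer[[1]]
    buffer <- buffer[-1]
    measured <- consume(head)
    proc_free_at <- max(proc_free_at, head$avail_t) + service_time(measured)
  }

  generated <- i
  hist <- table(factor(pred_labels, levels = model$levels))
  structure(
    list(
      epochs_generated = generated,
      epochs_captured = captured,
      epochs_processed = length(processed_idx),
      epochs_lost = lost,
      epoch_loss_fraction = if (generated > 0) {
        (generated - length(processed_idx)) / generated
      } else 0,
      label_histogram = stats::setNames(as.integer(hist), names(hist)),
      predictions = data.frame(
        epoch_index = processed_idx,
        label = pred_labels,
        proc_time_s = proc_times,
        stringsAsFactors = FALSE
      ),
      proc_time_total_s = sum(proc_times),
      epoch_length_s = epoch_length_s,
      processed_epochs = kept,
      error = err
    ),
    class = "stream_stats"
  )
}

#' @export
print.stream_stats <- function(x, ...) {
  live_report(x)
}

#' Render a live-style summary of streaming statistics
#'
#' Text rendering of the quantities the live display tracks: inferred
#' label counts, per-epoch processing time, and the distribution of epochs
#' per predicted label. Pure function of the stats (no mutation); lines are
#' suitable for an append-mode log in headless operation.
#'
#' @param stats A `stream_stats` object.
#' @param file Connection or filename passed to [cat()] (default stdout;
#'   use an opened append connection for logging).
#' @return `stats`, invisibly.
#' @export
live_report <- function(stats, file = "") {
  stopifnot(inherits(stats, "stream_stats"))
  lines <- c(
    sprintf("epochs generated/captured/processed: %d/%d/%d",
            stats$epochs_generated, stats$epochs_captured,
            stats$epochs_processed),
    sprintf("epoch loss: %d (%.1f%%)", stats$epochs_lost,
            100 * stats$epoch_loss_fraction),
    sprintf("processing time: total %.4f s, mean %.4f s/epoch",
            stats$proc_time_total_s,
            if (stats$epochs_processed > 0) {
              stats$proc_time_total_s / stats$epochs_processed
            } else 0),
    "label histogram:",
    if (length(stats$label_histogram)) {
      sprintf("  %-12s %d", names(stats$label_histogram),
              stats$label_histogram)
    } else "  <empty>",
    if (!is.null(stats$error)) sprintf("stream error: %s", stats$error)
  )
  cat(paste0(lines, collapse = "\n"), "\n", file = file)
  invisible(stats)
}

#' Plot the predicted-label histogram
#'
#' @param stats A `stream_stats` object.
#' @param path Optional PNG path; `NULL` draws on the current device.
#' @return `stats`, invisibly.
#' @export
plot_label_histogram <- function(stats, path = NULL) {
  stopifnot(inherits(stats, "stream_stats"))
  if (!is.null(path)) {
    grDevices::png(path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(stats$label_histogram,
                    main = "Epoch count per predicted label",
                    ylab = "epochs", las = 2)
  invisible(stats)
}

#' Collection-vs-processing timing profile
#'
#' For each batch size `n`, streams the first `n` epochs of the recording
#' through the engine, reporting the analytic epoch collection time
#' (`n * epoch_length_s`, the time a live source would need to produce the
#' samples), the measured processing time (preprocessing + features +
#' classification), and processing time as a percentage of collection
#' time. Processing time is cumulative, hence monotonically non-decreasing
#' in `n`.
#'
#' @param recording An [eeg_recording()] with at least `max(n_epochs)`
#'   full epochs.
#' @param model,baseline Trained model and baseline.
#' @param n_epochs Batch sizes (default `c(1, 10, 100)`).
#' @param epoch_length_s Epoch length in seconds (default 64).
#' @param ... Passed to [run_stream()].
#' @return Data.frame with columns `n_epochs`, `collection_time_s`,
#'   `processing_time_s`, `processing_pct_of_collection`.
#' @export
timing_profile <- function(recording, model, baseline,
                           n_epochs = c(1, 10, 100), epoch_length_s = 64,
                           ...) {
  rows <- lapply(n_epochs, function(n) {
    st <- run_stream(recording, epoch_length_s, model, baseline,
                     max_epochs = n, ...)
    data.frame(
      n_epochs = n,
      collection_time_s = n * epoch_length_s,
      processing_time_s = st$proc_time_total_s,
      processing_pct_of_collection =
        100 * st$proc_time_total_s / (n * epoch_length_s)
    )
  })
  do.call(rbind, rows)
}
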