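# Shared fixtures, built once per test run and cached. All synthetic, all
# generated in code under fixed seeds.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Small dataset for unit tests: 10 epochs/class of 16 s, default profiles.
small_fixture <- function() {
  fx("small", function() {
    spec <- synthetic_spec(epochs_per_class = 10, epoch_length_s = 16,
                           seed = 7)
    out <- generate_recording(spec)
    epochs <- segment_epochs(out$recording, 16, labels = out$labels$label)
    powers <- band_power_matrix(epochs)
    baseline <- compute_baseline(epochs, out$labels$subject, powers = powers)
    feats <- features_matrix(powers, baseline)
    model <- train_classifier(feats, out$labels$label, seed = 1)
    list(recording = out$recording, labels = out$labels, epochs = epochs,
         powers = powers, baseline = baseline, feats = feats, model = model)
  })
}

# Study-scale dataset: 100 epochs/class of 64 s (the training-set scale the
# separability and determinism checks run at).
study_fixture <- function() {
  fx("study", function() {
    spec <- synthetic_spec(epochs_per_class = 100, epoch_length_s = 64,
                           seed = 11)
    out <- generate_recording(spec)
    epochs <- segment_epochs(out$recording, 64, labels = out$labels$label)
    powers <- band_power_matrix(epochs)
    baseline <- compute_baseline(epochs, out$labels$subject, powers = powers)
    feats <- features_matrix(powers, baseline)
    model <- train_classifier(feats, out$labels$label, seed = 1)
    list(recording = out$recording, labels = out$labels, epochs = epochs,
         powers = powers, baseline = baseline, feats = feats, model = model)
  })
}

# A 100-epoch (25 per class) 64 s recording: 6400 s in total, the streaming
# batch the zero-loss and timing checks run on.
stream_fixture <- function() {
  fx("stream", function() {
    spec <- synthetic_spec(epochs_per_class = 25, epoch_length_s = 64,
                           seed = 4)
    generate_recording(spec)
  })
}

# Feature matrix from precomputed raw band powers (test-side shorthand for
# the internal fold-aware path).
features_matrix <- function(powers, baseline) {
  eegpipe:::features_from_powers(powers, baseline)
}

# Independent spectral oracle: band power fraction from a single raw
# periodogram (plain FFT), no Welch machinery shared with the implementation.
oracle_band_fraction <- function(x, fs, low, high) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f > 0 & f <= fs / 2
  sum(p[keep & f >= low & f <= high]) / sum(p[keep])
}

# Trapezoidal integral of a PSD estimate over its full frequency range.
psd_total_power <- function(psd) {
  d <- psd$density
  sum(diff(psd$freqs) * (d[-length(d)] + d[-1]) / 2)
}
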