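sine_epoch <- function(freq, secs = 64, fs = 256, amp = 1) {
  t <- (0:(secs * fs - 1)) / fs
  amp * sin(2 * pi * freq * t)
}

test_that("Welch PSD satisfies Parseval for deterministic and noise signals", {
  x <- sine_epoch(10)
  psd <- welch_psd(x, fs = 256)
  # unit sinusoid has variance 1/2
  expect_equal(psd_total_power(psd), 0.5, tolerance = 0.02)
  expect_equal(psd$resolution, 0.25)
  # white noise: integrated PSD matches sample variance within 5%
  set.seed(20)
  w <- rnorm(64 * 256, sd = 1.7)
  expect_equal(psd_total_power(welch_psd(w, fs = 256)), stats::var(w),
               tolerance = 0.05)
  # all-zero epoch: PSD identically zero
  expect_identical(unique(welch_psd(numeric(2048), fs = 256)$density), 0)
  # epoch shorter than one segment is rejected
  expect_error(welch_psd(numeric(512), fs = 256),
               class = "eegpipe_validation_error")
})

test_that("band powers localize sinusoids and superpose", {
  psd <- welch_psd(sine_epoch(10), fs = 256)
  scheme <- sub_band_scheme()
  expect_equal(band_power(psd, "alpha"), 0.5, tolerance = 0.02)
  for (b in setdiff(names(scheme), "alpha")) {
    expect_lt(band_power(psd, b), 0.01)
  }
  # two unit sinusoids: theta and alpha each carry ~0.5
  psd2 <- welch_psd(sine_epoch(5) + sine_epoch(10), fs = 256)
  expect_equal(band_power(psd2, "theta"), 0.5, tolerance = 0.02)
  expect_equal(band_power(psd2, "alpha"), 0.5, tolerance = 0.02)
  # zero PSD integrates to zero in every band
  psd0 <- welch_psd(numeric(2048), fs = 256)
  for (b in names(scheme)) expect_identical(band_power(psd0, b), 0)
  expect_error(band_power(psd, c(120, 140)),
               class = "eegpipe_validation_error")
})

test_that("the sub-band scheme enforces its invariants", {
  s <- sub_band_scheme()
  expect_named(s, c("delta", "theta", "alpha", "sigma", "beta", "gamma"))
  expect_error(sub_band_scheme(list(a = c(3, 1))),
               class = "eegpipe_validation_error")
  expect_error(sub_band_scheme(list(a = c(1, 5), b = c(4, 8))),
               class = "eegpipe_validation_error")
})

test_that("baseline powers are per-band means over leading subject epochs", {
  # constructed raw powers: epochs only carry positions here
  dummy_epochs <- replicate(12, list(), simplify = FALSE)
  bands <- names(sub_band_scheme())
  powers <- matrix(1, nrow = 12, ncol = 6, dimnames = list(NULL, bands))
  powers[, "alpha"] <- c(rep(1, 6), rep(3, 6)) # subject A then subject B
  subjects <- rep(c("A", "B"), each = 6)
  base <- compute_baseline(dummy_epochs, subjects, n_first = 5,
                           powers = powers)
  expect_equal(base$powers[["alpha"]], 2) # mean of 1.0 and 3.0 subject means
  expect_equal(base$n_epochs_used, 10)
  # recomputing from the persisted provenance recovers the same baseline
  again <- colMeans(powers[base$provenance$epoch_position, , drop = FALSE])
  expect_identical(again, base$powers)
  # subjects with too few epochs are rejected
  expect_error(compute_baseline(dummy_epochs, c(rep("A", 9), rep("B", 3)),
                                n_first = 5, powers = powers),
               class = "eegpipe_validation_error")
  powers0 <- powers
  powers0[, "gamma"] <- 0
  expect_error(compute_baseline(dummy_epochs, subjects, n_first = 5,
                                powers = powers0),
               class = "eegpipe_validation_error")
})

test_that("decibel normalization matches its closed form and inverts exactly", {
  expect_identical(db_normalize(2, 2), 0)
  expect_identical(db_normalize(20, 2), 10)
  expect_equal(db_normalize(4, 2), 10 * log10(2), tolerance = 1e-12)
  p <- c(0.3, 1, 7.5, 42)
  db <- db_normalize(p, 2.5)
  expect_equal(2.5 * 10^(db / 10), p, tolerance = 1e-12)
  expect_error(db_normalize(1, 0), class = "eegpipe_validation_error")
  expect_error(db_normalize(-1, 1), class = "eegpipe_validation_error")
  # floored, not -Inf, on silent input
  expect_true(is.finite(db_normalize(0, 1)))
})

test_that("feature vectors have the documented shape and limiting behavior", {
  sf <- small_fixture()
  fv <- extract_features(sf$epochs[[1]], sf$baseline)
  expect_length(fv, 7)
  expect_named(fv, c(paste0("db_", names(sub_band_scheme())),
                     "theta_alpha_ratio"))
  expect_true(all(is.finite(fv)))
  # deterministic: identical epoch + baseline give bit-identical features
  expect_identical(fv, extract_features(sf$epochs[[1]], sf$baseline))
  # pure 10 Hz sinusoid: theta/alpha ratio collapses toward zero
  ep <- list(samples = sine_epoch(10), fs = 256, length_s = 64, index = 0L)
  class(ep) <- "eeg_epoch"
  fv10 <- extract_features(ep, sf$baseline)
  expect_lt(fv10[["theta_alpha_ratio"]], 1e-6)
})

test_that("features are invariant under amplitude rescaling of the data", {
  sf <- small_fixture()
  c_scale <- 37.5
  scaled <- lapply(sf$epochs[1:8], function(e) {
    e$samples <- e$samples * c_scale
    e
  })
  powers_orig <- sf$powers[1:8, , drop = FALSE]
  powers_scaled <- band_power_matrix(scaled)
  # powers scale by c^2 ...
  expect_equal(powers_scaled, powers_orig * c_scale^2, tolerance = 1e-8)
  # ... so dB features against a baseline scaled the same way are unchanged
  base_scaled <- sf$baseline
  base_scaled$powers <- sf$baseline$powers * c_scale^2
  f_orig <- features_matrix(powers_orig, sf$baseline)
  f_scaled <- features_matrix(powers_scaled, base_scaled)
  expect_equal(f_scaled, f_orig, tolerance = 1e-8)
})

test_that("epochs statistically identical to the baseline sit near 0 dB", {
  sf <- small_fixture()
  prov <- sf$baseline$provenance$epoch_position
  f_base <- features_matrix(sf$powers[prov, , drop = FALSE], sf$baseline)
  db_cols <- grep("^db_", colnames(f_base))
  expect_lt(max(abs(colMeans(f_base[, db_cols]))), 1.5)
})

test_that("low-pass decimation keeps passband content and rejects aliases", {
  ep <- list(samples = sine_epoch(10), fs = 256, length_s = 64, index = 0L)
  class(ep) <- "eeg_epoch"
  down <- lowpass_downsample(ep, factor = 4)
  expect_identical(length(down$samples), 4096L)
  expect_identical(down$fs, 64)
  # a 10 Hz tone is far inside the new passband: power preserved
  expect_equal(stats::var(down$samples), 0.5, tolerance = 0.02)
  # DC-constant epoch passes through unchanged
  dc <- ep
  dc$samples <- rep(3, 16384)
  expect_equal(lowpass_downsample(dc, 4)$samples, rep(3, 4096),
               tolerance = 1e-6)
  # content above the new Nyquist is attenuated by >= 20 dB
  hi <- ep
  hi$samples <- sine_epoch(100)
  out <- lowpass_downsample(hi, 4)
  expect_lt(stats::var(out$samples) / stats::var(hi$samples), 0.01)
  expect_error(lowpass_downsample(ep, 3),
               class = "eegpipe_validation_error")
  expect_error(lowpass_downsample(ep, 0),
               class = "eegpipe_validation_error")
})
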