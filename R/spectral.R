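#' Frequency sub-band scheme
#'
#' The six named EEG frequency bands over which epoch power is integrated:
#' delta (1-3.5 Hz), theta (4-7.5 Hz), alpha (8-12 Hz), sigma (13-16 Hz),
#' beta (16.5-25 Hz) and gamma (30-35 Hz). The scheme deliberately has gaps
#' (3.5-4 Hz, 25-30 Hz, ...): frequencies between bands contribute to no
#' band.
#'
#' @param bands Named list mapping band name to a numeric `c(low, high)`
#'   pair in Hz. Bands must be non-overlapping with `low < high`.
#' @return Named list of band edges, classed `sub_band_scheme`.
#' @export
sub_band_scheme <- function(bands = list(
                              delta = c(1, 3.5), theta = c(4, 7.5),
                              alpha = c(8, 12), sigma = c(13, 16),
                              beta = c(16.5, 25), gamma = c(30, 35)
                            )) {
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2]) {
      stop_validation(sprintf("band '%s' must be c(low, high) with low < high", nm))
    }
  }
  edges <- do.call(rbind, bands)
  ord <- order(edges[, 1])
  edges <- edges[ord, , drop = FALSE]
  if (nrow(edges) > 1 && any(edges[-1, 1] < edges[-nrow(edges), 2])) {
    stop_validation("bands must be non-overlapping")
  }
  structure(bands, class = "sub_band_scheme")
}

#' Welch power spectral density of an epoch
#'
#' Averaged modified periodograms: the epoch is cut into `segment_s`-second
#' segments with fractional `overlap`, each segment is mean-removed,
#' Hamming-windowed and Fourier transformed, and the one-sided density
#' estimates are averaged. Density scaling is used, so integrating the
#' estimate over frequency recovers signal variance (Parseval).
#'
#' @param epoch An `eeg_epoch`, an `eeg_recording`, or a numeric vector (in
#'   which case `fs` must be given).
#' @param segment_s Segment length in seconds (default 4 s: 1024 samples at
#'   256 Hz, giving 0.25 Hz resolution, fine enough to resolve the 1 Hz and
#'   3.5 Hz band edges).
#' @param overlap Fractional overlap between consecutive segments
#'   (default 0.5).
#' @param fs Sampling rate in Hz; taken from `epoch` when it is an epoch or
#'   recording object.
#' @return Object of class `psd_estimate`: list with `freqs` (Hz, 0 to
#'   fs/2), `density` (power per Hz), and `resolution` (Hz).
#' @examples
#' t <- (0:(256 * 64 - 1)) / 256
#' psd <- welch_psd(sin(2 * pi * 10 * t), fs = 256)
#' sum(diff(psd$freqs) * (head(psd$density, -1) + tail(psd$density, -1)) / 2)
#' @export
welch_psd <- function(epoch, segment_s = 4, overlap = 0.5, fs = NULL) {
  if (inherits(epoch, c("eeg_epoch", "eeg_recording"))) {
    x <- epoch$samples
    fs <- epoch$fs
  } else {
    x <- as.numeric(epoch)
    if (is.null(fs)) stop_validation("`fs` must be given for a bare vector")
  }
  nseg <- as.integer(round(segment_s * fs))
  if (length(x) < nseg) {
    stop_validation(sprintf(
      "epoch has %d samples, shorter than one %g s segment (%d samples)",
      length(x), segment_s, nseg
    ))
  }
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- hamming_window(nseg)
  scale <- fs * sum(w^2)
  n_freq <- nseg %/% 2 + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(n_freq)])^2 / scale
    # one-sided: double everything except DC and (for even nseg) Nyquist
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[n_freq] <- 1
    acc <- acc + sp * dbl
  }
  density <- acc / length(starts)
  freqs <- seq(0, fs / 2, length.out = n_freq)
  structure(
    list(freqs = freqs, density = density, resolution = fs / nseg),
    class = "psd_estimate"
  )
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %d bins, 0-%g Hz, resolution %g Hz\n",
    length(x$freqs), max(x$freqs), x$resolution
  ))
  invisible(x)
}

#' Integrate a PSD over one frequency band
#'
#' Trapezoidal integral of the density over the grid points with
#' `low <= f <= high` (edges inclusive). The result has the units of signal
#' variance (power).
#'
#' @param psd A `psd_estimate`.
#' @param band Numeric `c(low, high)` in Hz, or a band name of `scheme`.
#' @param scheme Scheme used to resolve a band name.
#' @return Band power (non-negative scalar).
#' @export
band_power <- function(psd, band, scheme = sub_band_scheme()) {
  if (is.character(band)) {
    if (!band %in% names(scheme)) {
      stop_validation(sprintf("unknown band '%s'", band))
    }
    band <- scheme[[band]]
  }
  if (band[1] < min(psd$freqs) || band[2] > max(psd$freqs)) {
    stop_validation(sprintf(
      "band [%g, %g] Hz outside PSD support [%g, %g] Hz",
      band[1], band[2], min(psd$freqs), max(psd$freqs)
    ))
  }
  sel <- which(psd$freqs >= band[1] & psd$freqs <= band[2])
  if (length(sel) < 2L) {
    stop_validation("band narrower than the PSD frequency resolution")
  }
  f <- psd$freqs[sel]
  d <- psd$density[sel]
  sum(diff(f) * (d[-length(d)] + d[-1]) / 2)
}

#' Raw sub-band powers for a set of epochs
#'
#' Convenience wrapper computing the Welch PSD of each epoch and integrating
#' it over every band of the scheme. These raw powers are the `P` of the
#' decibel normalization and the inputs to baseline computation.
#'
#' @param epochs List of `eeg_epoch` objects.
#' @param scheme A [sub_band_scheme()].
#' @param segment_s,overlap Welch parameters, see [welch_psd()].
#' @return Numeric matrix, one row per epoch, one named column per band.
#' @export
band_power_matrix <- function(epochs, scheme = sub_band_scheme(),
                              segment_s = 4, overlap = 0.5) {
  out <- t(vapply(epochs, function(e) {
    psd <- welch_psd(e, segment_s = segment_s, overlap = overlap)
    vapply(names(scheme), function(b) band_power(psd, b, scheme), numeric(1))
  }, numeric(length(scheme))))
  colnames(out) <- names(scheme)
  out
}

#' Baseline sub-band powers from the first epochs of each training subject
#'
#' For each band, the baseline power is the mean band power over the pooled
#' set of each training subject's first `n_first` epochs ("first" in
#' recording order). This is the reference `P_baseline` of the decibel
#' normalization; computing it from training subjects only keeps test
#' epochs from leaking into the features.
#'
#' @param epochs List of `eeg_epoch` objects (training epochs).
#' @param subjects Character vector, one subject id per epoch. A single id
#'   (or `NULL`) treats all epochs as one subject.
#' @param n_first Number of leading epochs per subject (default 5).
#' @param scheme A [sub_band_scheme()].
#' @param segment_s,overlap Welch parameters.
#' @param powers Optional precomputed [band_power_matrix()] for `epochs`
#'   (rows aligned); avoids recomputing PSDs in cross-validation loops.
#' @return Object of class `baseline_powers`: list with `powers` (named
#'   per-band means, all > 0), `n_epochs_used`, and `provenance` (data.frame
#'   of subject and epoch position for every contributing epoch).
#' @export
compute_baseline <- function(epochs, subjects = NULL, n_first = 5,
                             scheme = sub_band_scheme(),
                             segment_s = 4, overlap = 0.5, powers = NULL) {
  n <- length(epochs)
  if (is.null(subjects)) subjects <- rep("S1", n)
  if (length(subjects) != n) {
    stop_validation("`subjects` must have one id per epoch")
  }
  if (is.null(powers)) {
    powers <- band_power_matrix(epochs, scheme, segment_s, overlap)
  }
  keep <- integer(0)
  for (s in unique(subjects)) {
    pos <- which(subjects == s)
    if (length(pos) < n_first) {
      stop_validation(sprintf(
        "subject '%s' contributes %d epochs, fewer than n_first = %d",
        s, length(pos), n_first
      ))
    }
    keep <- c(keep, pos[seq_len(n_first)])
  }
  base <- colMeans(powers[keep, , drop = FALSE])
  if (any(base <= 0)) {
    stop_validation("baseline power is zero in at least one band")
  }
  structure(
    list(
      powers = base,
      n_epochs_used = length(keep),
      provenance = data.frame(
        subject = subjects[keep],
        epoch_position = keep,
        stringsAsFactors = FALSE
      )
    ),
    class = "baseline_powers"
  )
}

#' @export
print.baseline_powers <- function(x, ...) {
  cat(sprintf(
    "<baseline_powers> from %d epochs (%d subject(s))\n",
    x$n_epochs_used, length(unique(x$provenance$subject))
  ))
  print(signif(x$powers, 4))
  invisible(x)
}

#' Decibel normalization of a band power against a baseline
#'
#' `dB = 10 * log10(P / P_baseline)`. Equal powers give 0 dB, a tenfold
#' power gives 10 dB. `P` is floored at `eps` before the logarithm so that
#' silent epochs yield a large negative but finite value.
#'
#' @param p Band power(s), >= 0.
#' @param p_baseline Baseline power (> 0), scalar or vector conformable
#'   with `p`.
#' @param eps Power floor in the same (arbitrary) units, default 1e-12.
#' @return Decibel value(s). Exactly invertible (above the floor) via
#'   `P = P_baseline * 10^(dB / 10)`.
#' @examples
#' db_normalize(2, 1) # 10 * log10(2) ~ 3.0103
#' @export
db_normalize <- function(p, p_baseline, eps = 1e-12) {
  if (any(p_baseline <= 0)) stop_validation("`p_baseline` must be > 0")
  if (any(p < 0)) stop_validation("`p` must be >= 0")
  10 * log10(pmax(p, eps) / p_baseline)
}

#' Extract the spectral feature vector of one epoch
#'
#' Seven features: the six dB-normalized sub-band powers (Welch band power
#' relative to the training baseline, in dB) and the ratio of raw theta to
#' raw alpha band power. The ratio is computed on raw powers (pre-dB); when
#' alpha power falls below `eps` the ratio is computed against the floor
#' and flagged via the `"alpha_floored"` attribute.
#'
#' @param epoch An `eeg_epoch`.
#' @param baseline A [compute_baseline()] result covering every band of
#'   `scheme`.
#' @param scheme A [sub_band_scheme()]; must contain `theta` and `alpha`.
#' @param segment_s,overlap Welch parameters.
#' @param eps Power floor for the dB transform and the ratio denominator.
#' @return Named numeric vector of length `length(scheme) + 1`
#'   (`db_<band>` ..., `theta_alpha_ratio`), all finite.
#' @export
extract_features <- function(epoch, baseline, scheme = sub_band_scheme(),
                             segment_s = 4, overlap = 0.5, eps = 1e-12) {
  psd <- welch_psd(epoch, segment_s = segment_s, overlap = overlap)
  p <- vapply(names(scheme), function(b) band_power(psd, b, scheme), numeric(1))
  features_from_powers(matrix(p, nrow = 1, dimnames = list(NULL, names(p))),
                       baseline, eps = eps)[1, ]
}

# Vectorized feature computation from a raw band-power matrix. Kept internal
# but used by cross_validate() and the streaming engine so fold-aware
# normalization does not recompute PSDs.
features_from_powers <- function(powers, baseline, eps = 1e-12) {
  bands <- colnames(powers)
  missing <- setdiff(bands, names(baseline$powers))
  if (length(missing)) {
    stop_validation(sprintf(
      "baseline lacks band(s): %s", paste(missing, collapse = ", ")
    ))
  }
  db <- sapply(bands, function(b) {
    db_normalize(powers[, b], baseline$powers[[b]], eps = eps)
  })
  if (is.null(dim(db))) db <- matrix(db, nrow = 1, dimnames = list(NULL, bands))
  colnames(db) <- paste0("db_", bands)
  alpha <- powers[, "alpha"]
  floored <- alpha < eps
  ratio <- powers[, "theta"] / pmax(alpha, eps)
  out <- cbind(db, theta_alpha_ratio = ratio)
  if (any(floored)) attr(out, "alpha_floored") <- which(floored)
  out
}

#' Anti-alias low-pass filter and decimate an epoch
#'
#' The preprocessing path for sample-domain classifiers: the epoch is
#' zero-phase low-pass filtered (8th-order Butterworth, cutoff at 0.8 times
#' the post-decimation Nyquist) and every `factor`-th sample is kept, so a
#' 64 s epoch at 256 Hz becomes a 64 s epoch at 64 Hz.
#'
#' @param epoch An `eeg_epoch` (or `eeg_recording`).
#' @param factor Integer decimation factor (default 4); must divide the
#'   sample count.
#' @return An object of the same class with `fs` divided by `factor`.
#' @export
lowpass_downsample <- function(epoch, factor = 4) {
  if (!is.numeric(factor) || factor < 1 || factor != round(factor)) {
    stop_validation("`factor` must be a positive integer")
  }
  factor <- as.integer(factor)
  x <- epoch$samples
  if (length(x) %% factor != 0L) {
    stop_validation(sprintf(
      "decimation factor %d does not divide the sample count %d",
      factor, length(x)
    ))
  }
  if (factor > 1L) {
    cutoff <- 0.8 * (epoch$fs / factor / 2)
    bf <- signal::butter(8, cutoff / (epoch$fs / 2), type = "low")
    x <- filtfilt_padded(bf, x)
    x <- x[seq(1L, length(x), by = factor)]
  }
  out <- epoch
  out$samples <- x
  out$fs <- epoch$fs / factor
  out
}
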