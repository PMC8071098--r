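#' Class-conditional spectral profile for synthetic EEG
#'
#' Describes one class (condition x vigilance state) as a set of target RMS
#' amplitudes, one per frequency sub-band, plus a broadband 1/f background
#' RMS. Epochs of that class are synthesized as the sum of independent
#' band-limited Gaussian noise components scaled to these RMS values.
#'
#' @param class_label One of [class_levels()].
#' @param band_rms Named numeric vector of target RMS amplitudes (arbitrary
#'   units), one entry per band of the active [sub_band_scheme()]. All
#'   values must be >= 0.
#' @param background_rms RMS of the broadband 1/f background component
#'   (>= 0).
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(class_label, band_rms, background_rms) {
  if (!class_label %in% class_levels()) {
    stop_validation(sprintf(
      "unknown class label '%s' (expected one of %s)",
      class_label, paste(class_levels(), collapse = ", ")
    ))
  }
  if (is.null(names(band_rms)) || any(!nzchar(names(band_rms)))) {
    stop_validation("`band_rms` must be a named vector of band RMS values")
  }
  if (any(!is.finite(band_rms)) || any(band_rms < 0)) {
    stop_validation("band RMS values must be finite and >= 0")
  }
  if (!is.finite(background_rms) || background_rms < 0) {
    stop_validation("`background_rms` must be finite and >= 0")
  }
  structure(
    list(
      class_label = class_label,
      band_rms = band_rms,
      background_rms = background_rms
    ),
    class = "class_profile"
  )
}

#' Default class profiles for the four-class sleep/injury problem
#'
#' Four spectral profiles chosen so that the classes are separable in the
#' feature space the classifier actually sees (dB-normalized sub-band powers
#' plus the theta/alpha power ratio):
#'
#' * sleep classes carry elevated delta RMS relative to wake (2.0 vs 1.0,
#'   i.e. a 6 dB delta-power contrast), mimicking slow-wave activity;
#' * injured (TBI) classes carry a shifted theta/alpha balance relative to
#'   sham (theta RMS 1.6 vs 1.0 and alpha RMS 0.7 vs 1.0, roughly a 7 dB
#'   shift in the theta/alpha power ratio).
#'
#' All profiles share a modest 1/f background. Amplitudes are arbitrary
#' units; only power ratios matter to the (scale-covariant) features.
#'
#' @return Named list of four `class_profile` objects, one per class.
#' @examples
#' p <- default_profiles()
#' names(p)
#' @export
default_profiles <- function() {
  base <- c(
    delta = 1.0, theta = 1.0, alpha = 1.0,
    sigma = 0.5, beta = 0.4, gamma = 0.25
  )
  tweak <- function(v, ...) {
    mods <- c(...)
    v[names(mods)] <- mods
    v
  }
  profs <- list(
    SHAM_WAKE  = class_profile("SHAM_WAKE", base, background_rms = 0.5),
    SHAM_SLEEP = class_profile("SHAM_SLEEP", tweak(base, delta = 2.0),
                               background_rms = 0.5),
    TBI_WAKE   = class_profile("TBI_WAKE", tweak(base, theta = 1.6, alpha = 0.7),
                               background_rms = 0.5),
    TBI_SLEEP  = class_profile("TBI_SLEEP",
                               tweak(base, delta = 2.0, theta = 1.6, alpha = 0.7),
                               background_rms = 0.5)
  )
  profs[class_levels()]
}

#' Specification for a synthetic labeled EEG recording
#'
#' @param profiles Named list of `class_profile` objects (default
#'   [default_profiles()]); classes present in the recording.
#' @param fs Sampling rate in Hz; must exceed twice the highest band edge of
#'   `scheme`. Default 256, the rate of the rodent recordings this module
#'   emulates.
#' @param epoch_length_s Seconds per labeled block; conventionally 16, 32
#'   or 64.
#' @param epochs_per_class Number of epochs generated for each class
#'   (>= 1).
#' @param subjects_per_group Number of synthetic subjects per condition
#'   group (sham / TBI); epochs of a group are attributed round-robin to its
#'   subjects, giving the multi-animal structure baseline computation
#'   expects.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   recording.
#' @param scheme Sub-band scheme the `band_rms` names refer to.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(profiles = default_profiles(), fs = 256,
                           epoch_length_s = 64, epochs_per_class = 25,
                           subjects_per_group = 3, seed = 1L,
                           scheme = sub_band_scheme()) {
  if (!length(profiles)) stop_validation("`profiles` must be non-empty")
  for (p in profiles) {
    if (!inherits(p, "class_profile")) {
      stop_validation("every element of `profiles` must be a `class_profile`")
    }
    unknown <- setdiff(names(p$band_rms), names(scheme))
    if (length(unknown)) {
      stop_validation(sprintf(
        "profile '%s' names bands absent from the scheme: %s",
        p$class_label, paste(unknown, collapse = ", ")
      ))
    }
  }
  top_edge <- max(vapply(scheme, function(b) b[2], numeric(1)))
  if (fs <= 2 * top_edge) {
    stop_validation(sprintf(
      "fs = %g Hz violates the Nyquist requirement fs > %g Hz", fs, 2 * top_edge
    ))
  }
  if (epochs_per_class < 1) stop_validation("`epochs_per_class` must be >= 1")
  if (subjects_per_group < 1) stop_validation("`subjects_per_group` must be >= 1")
  structure(
    list(
      profiles = profiles, fs = fs, epoch_length_s = epoch_length_s,
      epochs_per_class = epochs_per_class,
      subjects_per_group = subjects_per_group,
      seed = as.integer(seed), scheme = scheme
    ),
    class = "synthetic_spec"
  )
}

#' Generate a labeled synthetic single-channel EEG recording
#'
#' Produces a recording of `epochs_per_class * length(profiles)` consecutive
#' blocks of `epoch_length_s` seconds, each carrying one class label. A
#' block is the sum of independent band-limited noise components (zero-phase
#' 4th-order Butterworth band-pass of white Gaussian noise, scaled to the
#' profile's per-band RMS) and a 1/f background. Block order is shuffled
#' (seeded) so cross-validation folds are not trivially temporal. Epochs are
#' attributed to synthetic subjects round-robin within each condition group.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `recording` (an [eeg_recording()]) and
#'   `labels`, a data.frame with columns `epoch_index` (0-based), `label`
#'   and `subject`.
#' @examples
#' spec <- synthetic_spec(epochs_per_class = 2, epoch_length_s = 16)
#' out <- generate_recording(spec)
#' recording_duration(out$recording) # 2 * 4 * 16 = 128 s
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n_per <- as.integer(round(spec$epoch_length_s * spec$fs))
  classes <- vapply(spec$profiles, function(p) p$class_label, character(1))
  plan <- data.frame(
    label = rep(classes, each = spec$epochs_per_class),
    stringsAsFactors = FALSE
  )
  # subject attribution: round-robin within each condition group
  plan$subject <- NA_character_
  for (grp in c("SHAM", "TBI")) {
    in_grp <- grepl(paste0("^", grp), plan$label)
    if (any(in_grp)) {
      ids <- sprintf("%s_%d", grp, seq_len(spec$subjects_per_group))
      plan$subject[in_grp] <- rep_len(ids, sum(in_grp))
    }
  }
  plan <- plan[sample.int(nrow(plan)), , drop = FALSE]

  blocks <- vector("list", nrow(plan))
  prof_by_label <- stats::setNames(spec$profiles, classes)
  for (i in seq_len(nrow(plan))) {
    blocks[[i]] <- synth_epoch_block(
      prof_by_label[[plan$label[i]]], n_per, spec$fs, spec$scheme
    )
  }
  rec <- eeg_recording(unlist(blocks, use.names = FALSE), fs = spec$fs,
                       channel_name = "EEG_synth")
  labels <- data.frame(
    epoch_index = seq_len(nrow(plan)) - 1L,
    label = plan$label,
    subject = plan$subject,
    stringsAsFactors = FALSE
  )
  rownames(labels) <- NULL
  list(recording = rec, labels = labels)
}

# One epoch block: sum of band-limited components plus 1/f background.
synth_epoch_block <- function(profile, n, fs, scheme) {
  x <- numeric(n)
  for (band in names(profile$band_rms)) {
    rms <- profile$band_rms[[band]]
    if (rms <= 0) next
    edges <- scheme[[band]]
    comp <- bandlimited_noise(n, fs, edges[1], edges[2])
    x <- x + comp * (rms / stats::sd(comp))
  }
  if (profile$background_rms > 0) {
    bg <- pink_noise(n)
    x <- x + bg * (profile$background_rms / stats::sd(bg))
  }
  x
}

# White Gaussian noise band-passed with a zero-phase 4th-order Butterworth.
bandlimited_noise <- function(n, fs, low, high) {
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  filtfilt_padded(bf, stats::rnorm(n))
}

# Zero-phase filtering with odd-extension padding at both ends, which keeps
# the forward-backward filter free of start-up transients (constants pass
# through exactly up to numerical noise).
filtfilt_padded <- function(filt, x, n_pad = 256L) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  if (n_pad < 1L) return(signal::filtfilt(filt, x))
  head_ext <- 2 * x[1] - x[(n_pad + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - n_pad)]
  y <- signal::filtfilt(filt, c(head_ext, x, tail_ext))
  y[(n_pad + 1L):(n_pad + n)]
}

# 1/f ("pink") noise via spectral shaping: Gaussian spectrum with amplitude
# proportional to 1/sqrt(f), zero DC.
pink_noise <- function(n) {
  n_half <- n %/% 2
  f <- seq_len(n_half)
  amp <- 1 / sqrt(f)
  phases <- stats::runif(n_half) * 2 * pi
  spec <- complex(modulus = amp * stats::rnorm(n_half, mean = 1, sd = 0.2),
                  argument = phases)
  full <- complex(length.out = n)
  full[2:(n_half + 1)] <- spec
  if (n %% 2 == 0) {
    full[n_half + 1] <- complex(real = Re(full[n_half + 1]), imaginary = 0)
    full[(n_half + 2):n] <- Conj(spec[(n_half - 1):1])
  } else {
    full[(n_half + 2):n] <- Conj(spec[n_half:1])
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}
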