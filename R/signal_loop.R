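#' Quantizer specification for an emulated converter
#'
#' Describes an ideal uniform quantizer standing in for a hardware
#' converter: `bits` of resolution over a full-scale voltage range, codes
#' `0 .. 2^bits - 1`. Defaults match the emulated playback chain: a 12-bit
#' DAC for signal generation and a 10-bit ADC for capture, both on a
#' 0-3.3 V rail.
#'
#' @param bits Resolution in bits (>= 1).
#' @param v_min,v_max Full-scale range in volts, `v_max > v_min`.
#' @return Object of class `quantizer_spec`.
#' @export
quantizer_spec <- function(bits, v_min = 0, v_max = 3.3) {
  if (!is.numeric(bits) || bits < 1 || bits != round(bits)) {
    stop_validation("`bits` must be a positive integer")
  }
  if (!(v_max > v_min)) stop_validation("`v_max` must exceed `v_min`")
  structure(
    list(bits = as.integer(bits), v_min = v_min, v_max = v_max,
         n_codes = 2^as.integer(bits)),
    class = "quantizer_spec"
  )
}

#' @export
print.quantizer_spec <- function(x, ...) {
  cat(sprintf("<quantizer_spec> %d-bit, %g..%g V (step %.6g V)\n",
              x$bits, x$v_min, x$v_max, quantizer_step(x)))
  invisible(x)
}

#' Voltage step of a quantizer
#'
#' Code-to-voltage convention: code `k` maps to
#' `v_min + k * (v_max - v_min) / (2^bits - 1)`, so code 0 is `v_min` and
#' the top code is `v_max`; the step is the span divided by
#' `2^bits - 1`.
#'
#' @param spec A [quantizer_spec()].
#' @return Step size in volts.
#' @export
quantizer_step <- function(spec) {
  (spec$v_max - spec$v_min) / (spec$n_codes - 1)
}

round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Emulate digital-to-analog signal generation
#'
#' Affine-maps samples from their declared amplitude range onto the
#' converter's voltage range, rounds to the nearest of the `2^bits` codes
#' (half away from zero), and emits the code voltages. Samples outside the
#' declared range are clipped to the rails and counted.
#'
#' @param samples Finite numeric vector (amplitude units).
#' @param spec A [quantizer_spec()] (12-bit by default).
#' @param amp_range Declared amplitude range `c(min, max)` mapped onto the
#'   full voltage range; defaults to the sample range.
#' @return Object of class `quantized_signal`: list with `voltages`,
#'   `codes`, `clipped` (count), `spec` and `amp_range`.
#' @export
dac_emulate <- function(samples, spec = quantizer_spec(12),
                        amp_range = range(samples)) {
  if (!all(is.finite(samples))) stop_validation("samples must be finite")
  if (!(amp_range[2] > amp_range[1])) {
    stop_validation("degenerate amplitude range: max must exceed min")
  }
  v <- spec$v_min + (samples - amp_range[1]) / (amp_range[2] - amp_range[1]) *
    (spec$v_max - spec$v_min)
  clipped <- sum(v < spec$v_min | v > spec$v_max)
  v <- pmin(pmax(v, spec$v_min), spec$v_max)
  step <- quantizer_step(spec)
  codes <- round_half_away((v - spec$v_min) / step)
  codes <- pmin(pmax(codes, 0), spec$n_codes - 1)
  structure(
    list(
      voltages = spec$v_min + codes * step,
      codes = as.integer(codes),
      clipped = as.integer(clipped),
      spec = spec,
      amp_range = amp_range
    ),
    class = "quantized_signal"
  )
}

#' Emulate analog-to-digital capture
#'
#' Quantizes a voltage series to the converter's codes (voltages outside
#' the rails are clipped and counted) and maps codes back to amplitude
#' units through the inverse of the generation-side affine map.
#'
#' @param voltages Numeric voltage series.
#' @param spec A [quantizer_spec()] (10-bit by default).
#' @param fs Sampling rate in Hz of the returned recording.
#' @param amp_range Amplitude range corresponding to the full voltage
#'   range (the declared range used on the generation side).
#' @return List with `recording` (an [eeg_recording()] in amplitude units)
#'   and `clipped` (count).
#' @export
adc_emulate <- function(voltages, spec = quantizer_spec(10), fs = 256,
                        amp_range = c(0, 1)) {
  if (!(amp_range[2] > amp_range[1])) {
    stop_validation("degenerate amplitude range: max must exceed min")
  }
  clipped <- sum(voltages < spec$v_min | voltages > spec$v_max)
  v <- pmin(pmax(voltages, spec$v_min), spec$v_max)
  step <- quantizer_step(spec)
  codes <- pmin(pmax(round_half_away((v - spec$v_min) / step), 0),
                spec$n_codes - 1)
  vq <- spec$v_min + codes * step
  amps <- amp_range[1] + (vq - spec$v_min) / (spec$v_max - spec$v_min) *
    (amp_range[2] - amp_range[1])
  list(
    recording = eeg_recording(amps, fs = fs, channel_name = "EEG_loop"),
    clipped = as.integer(clipped)
  )
}

#' Mean squared error between observed and expected sample series
#'
#' `MSE = (1/n) * sum((Y_i - Yhat_i)^2)` over aligned, equal-length series:
#' zero iff the series are identical, and `c^2` for a constant offset `c`.
#'
#' @param observed Regenerated (captured) sample series `Y`.
#' @param expected Stored reference series `Yhat`.
#' @return Non-negative scalar.
#' @examples
#' signal_mse(c(1, 2), c(0, 0)) # 2.5
#' @export
signal_mse <- function(observed, expected) {
  if (length(observed) == 0) stop_validation("empty series")
  if (length(observed) != length(expected)) {
    stop_validation(sprintf(
      "length mismatch: observed %d vs expected %d",
      length(observed), length(expected)
    ))
  }
  mean((observed - expected)^2)
}

#' Verify signal fidelity through the emulated playback loop
#'
#' Runs a recording through the emulated DAC (generation) and ADC
#' (capture), aligns stored and regenerated samples by index (the emulated
#' loop introduces no delay; a lag search hook is available for
#' phase-shifting hardware paths), and reports the MSE together with
#' clipping counts. The recording's amplitude extremes are mapped
#' `headroom` fraction inside the voltage rails so a clean signal never
#' clips.
#'
#' @param recording An [eeg_recording()].
#' @param dac_spec,adc_spec [quantizer_spec()]s (12-bit / 10-bit
#'   defaults).
#' @param headroom Fraction of the voltage span kept clear at each rail
#'   (default 0.05).
#' @param lag_search Maximum lag (samples) to search for the alignment
#'   maximizing cross-correlation; 0 (default) aligns by index.
#' @return Object of class `signal_comparison`: list with `expected`,
#'   `observed`, `n`, `mse`, `lag`, `clipped_dac`, `clipped_adc`,
#'   `amp_range`.
#' @export
verify_playback <- function(recording, dac_spec = quantizer_spec(12),
                            adc_spec = quantizer_spec(10), headroom = 0.05,
                            lag_search = 0) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$samples
  r <- range(x)
  if (r[2] <= r[1]) r <- r + c(-1, 1) * max(1, abs(r[1]))
  # declared range widened so the signal sits `headroom` inside the rails
  span <- r[2] - r[1]
  usable <- 1 - 2 * headroom
  amp_range <- c(r[1] - span * headroom / usable,
                 r[2] + span * headroom / usable)

  dac <- dac_emulate(x, dac_spec, amp_range = amp_range)
  adc <- adc_emulate(dac$voltages, adc_spec, fs = recording$fs,
                     amp_range = amp_range)
  y <- adc$recording$samples

  lag <- 0L
  if (lag_search > 0) {
    lags <- -lag_search:lag_search
    score <- vapply(lags, function(l) {
      idx <- seq_along(x)
      obs <- if (l >= 0) c(rep(NA, l), y)[idx] else y[idx - l]
      stats::cor(x, obs, use = "complete.obs")
    }, numeric(1))
    lag <- lags[which.max(score)]
    if (lag > 0) y <- c(rep(y[1], lag), y)[seq_along(x)]
    if (lag < 0) y <- c(y[(-lag + 1):length(y)], rep(y[length(y)], -lag))
  }

  structure(
    list(
      expected = x,
      observed = y,
      n = length(x),
      mse = signal_mse(y, x),
      lag = lag,
      clipped_dac = dac$clipped,
      clipped_adc = adc$clipped,
      amp_range = amp_range
    ),
    class = "signal_comparison"
  )
}

#' @export
print.signal_comparison <- function(x, ...) {
  cat(sprintf(
    "<signal_comparison> n = %d, MSE = %.6g, clipped DAC/ADC = %d/%d\n",
    x$n, x$mse, x$clipped_dac, x$clipped_adc
  ))
  invisible(x)
}

#' Closed-form quantization-noise bound for the playback loop
#'
#' Each ideal uniform quantizer contributes at most `step^2 / 12` of
#' mean-square error under the standard uniform-error model (and at most
#' `step^2 / 4` in the worst case); the loop bound is the sum over both
#' converters, expressed in amplitude units via the declared amplitude
#' range.
#'
#' @param dac_spec,adc_spec [quantizer_spec()]s.
#' @param amp_range Declared amplitude range of the mapping.
#' @param worst_case Use the worst-case `step^2 / 4` per converter instead
#'   of the uniform-model `step^2 / 12`.
#' @return MSE bound in squared amplitude units.
#' @export
quantization_mse_bound <- function(dac_spec, adc_spec, amp_range,
                                   worst_case = FALSE) {
  amp_step <- function(spec) {
    (amp_range[2] - amp_range[1]) / (spec$n_codes - 1)
  }
  div <- if (worst_case) 4 else 12
  amp_step(dac_spec)^2 / div + amp_step(adc_spec)^2 / div
}
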