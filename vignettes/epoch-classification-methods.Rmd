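---
title: "Methods: spectral epoch classification and streaming capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral epoch classification and streaming capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model each
module implements, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data validation
does and does not establish.

## The classification model

The unit of analysis is the **epoch**: a non-overlapping window of 16, 32
or 64 s cut from a single-channel EEG recording sampled at 256 Hz. Each
epoch is mapped to seven features:

1. Six **dB-normalized sub-band powers**. The power spectral density (PSD)
   is estimated by Welch's method and integrated (trapezoidally, band edges
   inclusive) over delta (1–3.5 Hz), theta (4–7.5 Hz), alpha (8–12 Hz),
   sigma (13–16 Hz), beta (16.5–25 Hz) and gamma (30–35 Hz). The scheme has
   deliberate gaps (3.5–4, 12–13, 16–16.5, 25–30 Hz); frequencies between
   bands contribute to no feature. Each band power $P$ is expressed as
   $\mathrm{dB} = 10\log_{10}(P/P_\text{baseline})$, which makes the
   features invariant to overall amplitude calibration (powers and baseline
   both scale as $c^2$ under a gain $c$) and compresses the natural
   $1/f$ decline of EEG power so that high-frequency changes remain
   visible.
2. The **theta/alpha ratio**, computed on raw (pre-dB) powers. It is
   baseline-free and scale-invariant by construction.

The classifier is a multiclass gradient-boosted tree ensemble over the four
classes (sham/injured condition × wake/sleep state). "Default"
hyperparameters are pinned as an explicit snapshot
(`classifier_defaults()`: 100 rounds, learning rate 0.3, depth 6, no
subsampling) because library defaults drift across versions; training is
single-threaded and seeded so that identical data and seed give
bit-identical models on any platform — the property that lets a model be
trained on a workstation and deployed on an embedded target with identical
outputs.

## Baseline computation and leakage control

$P_\text{baseline}$ is, per band, the mean band power over the pooled
*first five* epochs (recording order) of every training subject. Two
consequences are easy to miss:

* The baseline is a **training-set quantity**. In cross-validation it is
  recomputed inside every fold from training-fold epochs only; test epochs
  never influence the normalization of the features they are scored with.
  Since the folds split pooled epochs at random, "first five of each
  subject" is read as *each subject's first five epochs that fall in the
  training fold*. This is the leakage-free reading of a baseline defined
  per training subject.
* The baseline pools all classes. dB features are therefore centred on the
  cross-class mean spectrum, not on a per-class reference; class contrasts
  survive as positive/negative dB offsets.

`cross_validate()` accordingly takes epochs (plus labels and subject ids),
not a precomputed feature matrix: fold-aware normalization forces feature
assembly inside the fold loop. Raw band powers are computed once and reused
across folds, since only the (cheap) dB step depends on the fold.

Cross-validation folds split pooled epochs at random (seeded), not by
subject; with few subjects, subject-grouped splits are the stricter
protocol for generality claims, and `group_by_subject = TRUE` provides
them as an option.

## Welch estimator choices

Segment length is 4 s (1024 samples at 256 Hz) with 50 % overlap and a
Hamming window — the segment length is chosen so the 0.25 Hz resolution
resolves the 1 Hz and 3.5 Hz band edges, and it is exposed as a parameter.
Each segment is mean-removed before windowing, and density scaling is used,
so the integral of the one-sided PSD over frequency recovers the signal
variance (Parseval); the test suite checks this to within 2 % for
sinusoids and 5 % for white noise at 64 s. Powers are floored at
$\varepsilon = 10^{-12}$ (arbitrary units²) before the logarithm so silent
epochs produce large negative but finite dB values; the theta/alpha ratio
uses the same floor in its denominator and flags the epoch when alpha
power sits below it.

The sample-domain preprocessing path (`lowpass_downsample()`) for
classifiers that consume raw waveforms applies a zero-phase 8th-order
Butterworth low-pass at 0.8× the post-decimation Nyquist, then keeps every
4th sample. Zero-phase filtering throughout (synthesis band-passes
included) uses odd-extension padding at the ends, which removes
forward–backward start-up transients; constants pass through the
decimator unchanged to numerical precision.

## The synthetic generator

Real injured-rodent EEG is not redistributable, so validation runs on a
generator whose defaults define the study conditions. Each epoch block is
the sum of independent band-limited components — white Gaussian noise
band-passed with a zero-phase 4th-order Butterworth per sub-band, scaled
to a per-class target RMS — plus a $1/f$ background synthesized
spectrally. This is the simplest generative model whose sufficient
statistics match what the feature extractor measures: the classifier sees
only band powers, so class structure is injected directly as band-power
contrasts. Default profiles (`default_profiles()`) encode sleep as a 6 dB
delta-power elevation over wake (RMS 2.0 vs 1.0) and injury as a ~7 dB
shift of the theta/alpha power ratio (theta RMS 1.6 vs 1.0, alpha 0.7 vs
1.0) — contrasts of at least 3 dB, comfortably above the band-power
estimation noise of a 64 s epoch. Blocks are shuffled (seeded) so
cross-validation folds are not trivially temporal, and epochs are
attributed round-robin to three synthetic subjects per condition group so
baseline computation exercises its per-subject rule. Amplitudes are
arbitrary units throughout; the features are scale-invariant, so no µV
calibration is asserted.

What passing tests on this generator shows: the pipeline recovers class
structure that is present in sub-band powers, at the effect sizes the
profiles state, under the exact estimator the features use. What it does
not show: performance on real EEG, whose nonstationarity, artifacts,
inter-subject variability and non-power class cues (phase, transients,
spindles) the generator deliberately omits. Accuracy figures on synthetic
data are properties of the harness, not claims about any animal dataset.

## Streaming engine

The real-time contract is behavioral: capture accumulates samples into
epoch buckets; completed epochs enter a bounded FIFO buffer (default
capacity 16); an independent processing path drains the buffer and handles
each epoch exactly once; no epoch is lost while mean per-epoch processing
time stays below the epoch collection time. The implementation realizes
this as a deterministic discrete-event simulation on a virtual timeline:
epoch $i$ completes capture at $(i{+}1)\cdot L$ seconds, and the processor
starts an epoch as soon as it is both idle and the epoch is buffered.
Per-epoch processing time (preprocessing + features + prediction) is
measured on the wall clock and used as the service time, so the engine's
loss behavior reflects real processing cost while remaining reproducible.
Overflow is explicit and counted, never silent: when a completed epoch
finds the buffer full, the oldest buffered epoch is dropped (drop-oldest
keeps the stream current, the natural choice for a live display). A
testing hook (`simulated_proc_time_s`) overrides the service time to
exercise the overflow policy deterministically; the suite pins the exact
drop schedule for a processor twice as slow as collection. Accelerated
playback (no wall-clock sleeping) is the default so a 6400 s batch streams
in under a second of real time; `pacing = TRUE` restores real-time pacing.

## Quantizer playback loop

The emulated generation/capture chain models both converters as ideal
uniform quantizers: code $k \mapsto v_\min + k\,(v_\max -
v_\min)/(2^{\text{bits}}-1)$, rounding half away from zero, 12-bit
generation and 10-bit capture on a 0–3.3 V rail by default. The
recording's amplitude extremes are mapped 5 % inside the rails
(headroom), so a clean signal never clips; clipping, when induced, is
counted and reported. Loop fidelity is the MSE between stored and
regenerated samples, compared against the closed-form quantization-noise
bound ($\Delta^2/12$ per converter under the uniform-error model,
$\Delta^2/4$ worst-case). Alignment is by sample index — the emulated
loop introduces no delay — with an optional cross-correlation lag search
for phase-shifting hardware paths. One subtlety: refining a *single*
converter lowers the MSE only down to the other converter's noise floor,
where small non-monotone fluctuations are expected of a quantizer
cascade; the monotonicity property is therefore stated and tested for
joint refinement of both converters.

## Problem sizes and runtime

The validation suite runs at desk scale, chosen so the full pipeline is
exercised end to end: a 400-epoch training set (100 per class, 64 s at
256 Hz, ~26 min of signal), a 100-epoch (6400 s) streaming batch
processed five times, and 10-fold cross-validation on the 400-epoch set
(including a permuted-label control, which must land at the 4-class
chance level). Unit tests use 16 s epochs and smaller batches. The
acceptance script regenerates everything from a single seed at these same
sizes.

## Known limitations

* EDF support is deliberately minimal: single channel, contiguous 16-bit
  records, one record per second; no EDF+ annotations, no BDF.
* The fine-to-coarse label aggregation rule (majority over 4 s scores,
  ties toward wake) is a documented convention; other purity rules are
  defensible.
* The streaming engine emulates concurrency deterministically rather than
  using OS threads; the contract (bounded buffer, exactly-once,
  counted loss) is what is tested, and a thread-based backend would have
  to satisfy the same tests.
* The classifier interface is pluggable at the feature-matrix level, but
  only the gradient-boosted-tree path ships; sample-domain models are
  supported through `lowpass_downsample()` preprocessing only.
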