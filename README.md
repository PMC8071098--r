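# eegpipe

Real-time single-channel EEG epoch classification at desk scale: spectral
sub-band features, a four-class sleep/injury classifier, a lossless
capture-while-processing streaming engine, and an emulated DAC→ADC playback
loop for signal-fidelity verification.

## The problem

Mild traumatic brain injury (mTBI) leaves spectral signatures in the EEG,
and portable single-channel systems can screen for it continuously if the
software can classify epochs as fast as they are collected. `eegpipe`
implements that pipeline for researchers prototyping such systems: it
segments a 256 Hz single-channel recording into non-overlapping epochs
(16/32/64 s), extracts decibel-normalized spectral features, classifies each
epoch into one of four classes — sham wake, sham sleep, TBI wake, TBI
sleep — and streams epochs through a bounded producer/consumer buffer so
capture never waits on classification. Because real injured-animal EEG is
rarely shareable, a first-class synthetic generator produces labeled
recordings with class-specific spectral profiles for development and
validation.

## The method

For each epoch the power spectral density is estimated by Welch's method
(Hamming window, 4 s segments, 50 % overlap) and integrated over six
sub-bands: delta (1–3.5 Hz), theta (4–7.5 Hz), alpha (8–12 Hz), sigma
(13–16 Hz), beta (16.5–25 Hz), gamma (30–35 Hz). Each band power *P* is
normalized against a training baseline,

    dB = 10 · log10(P / P_baseline),

where *P*<sub>baseline</sub> is the per-band mean power over the first five
epochs of every training subject. The seven features (six dB powers plus
the raw theta/alpha power ratio) feed a gradient-boosted-tree classifier
(XGBoost, pinned defaults, single-threaded for bit-reproducibility).
Validation is 10-fold cross-validation over randomly pooled epochs, with
the baseline recomputed inside each fold from training epochs only.
Signal fidelity of the emulated 12-bit DAC → 10-bit ADC playback chain is
measured as the mean squared error between stored and regenerated samples,

    MSE = (1/n) · Σ (Yᵢ − Ŷᵢ)²,

and checked against the closed-form quantization-noise bound.

## Worked example

```r
library(eegpipe)

spec <- synthetic_spec(epochs_per_class = 25, epoch_length_s = 64, seed = 1)
sim  <- generate_recording(spec)
sim$recording
#> <eeg_recording> channel 'EEG_synth': 1638400 samples @ 256 Hz (6400.0 s)

epochs <- segment_epochs(sim$recording, 64, labels = sim$labels$label)
cross_validate(epochs, sim$labels$label, sim$labels$subject, k = 10, seed = 1)
#> <cv_report> 10-fold CV: mean accuracy 0.9800 (folds 1.000 0.900 1.000 ...)
#>            mean_precision mean_recall
#> SHAM_SLEEP          1.000      1.0000
#> SHAM_WAKE           0.975      1.0000
#> TBI_SLEEP           0.975      1.0000
#> TBI_WAKE            1.000      0.9167
```

The 6400 s recording holds 100 labeled 64 s epochs; 10-fold cross-validation
recovers the four synthetic classes with mean accuracy 0.98, and the
per-class precision/recall table shows where the (rare) confusions fall.
Training a model and streaming the same recording through the
capture/processing engine:

```r
powers   <- band_power_matrix(epochs)
baseline <- compute_baseline(epochs, sim$labels$subject, powers = powers)
feats    <- t(vapply(epochs, extract_features, numeric(7), baseline = baseline))
model    <- train_classifier(feats, sim$labels$label, seed = 1)

run_stream(sim$recording, 64, model, baseline)
#> epochs generated/captured/processed: 100/100/100
#> epoch loss: 0 (0.0%)
#> processing time: total 0.2630 s, mean 0.0026 s/epoch
#> label histogram:
#>   SHAM_SLEEP   25
#>   SHAM_WAKE    25
#>   TBI_SLEEP    25
#>   TBI_WAKE     25

verify_playback(sim$recording, quantizer_spec(12), quantizer_spec(10))
#> <signal_comparison> n = 1638400, MSE = 0.000208824, clipped DAC/ADC = 0/0
```

Every generated epoch was captured and processed (0 % epoch loss), mean
processing time was ~3 ms per 64 s epoch — far below the 64 s collection
time, which is what makes lossless real-time operation possible — and the
emulated playback loop reproduces the stored signal to within the
quantization noise of the 10-bit capture stage.

A command-line front end over the same functions lives in
`inst/cli/eegpipe.R` (`generate`, `train`, `stream`, `verify`
subcommands, YAML configuration).

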