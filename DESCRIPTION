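Package: eegpipe
Title: Real-Time Single-Channel EEG Epoch Classification with Streaming
    Capture and Quantizer Playback Emulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Segments single-channel electroencephalogram (EEG) recordings
    into fixed-length epochs, extracts decibel-normalized Welch spectral
    sub-band power features, and classifies epochs into four classes
    (sham/injured condition crossed with wake/sleep state) with a
    gradient-boosted-tree model under fold-aware cross-validation. Includes
    a synthetic labeled EEG generator with class-specific spectral
    profiles, a European Data Format (EDF) reader and writer, a lossless
    capture-while-processing streaming engine with a bounded epoch buffer,
    and an emulated digital-to-analog / analog-to-digital playback loop
    verified by mean squared error against the stored signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
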