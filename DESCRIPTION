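Package: emgal
Title: Active Learning for Myoelectric Grip Decoder Recalibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline pool-based active-learning pipeline for surface
    electromyography (sEMG) grip decoding. Provides a seeded two-session
    synthetic EMG generator with controllable between-session drift, signal
    conditioning (band-limited up-sampling, Hampel despiking, zero-phase
    Butterworth band-pass), sliding-window waveform-length features, a linear
    discriminant analysis decoder with per-iteration z-score normalization,
    and query strategies for decoder recalibration: random sampling, least
    confidence, smallest margin, entropy, naive top-n batches, and ranked
    batch-mode active learning. An experiment harness runs the
    query-annotate-retrain-evaluate loop and returns learning curves and
    class-wise query statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
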