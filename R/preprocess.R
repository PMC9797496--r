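#' Sliding-window specification
#'
#' Window length and step in milliseconds, resolved against a sampling rate.
#' Defaults follow the standard myoelectric-decoding configuration: 128 ms
#' windows (256 samples at 2 kHz) advanced in 50 ms steps (100 samples).
#'
#' @param length_ms Window duration in ms (> 0).
#' @param step_ms Window increment in ms (0 < step_ms <= length_ms).
#' @param fs_hz Sampling rate the spec resolves against; the resolved sample
#'   counts `length_ms * fs / 1000` and `step_ms * fs / 1000` must be whole
#'   numbers.
#' @return An object of class `window_spec` with resolved `length_n` and
#'   `step_n` sample counts.
#' @examples
#' window_spec()$length_n  # 256 samples
#' @export
window_spec <- function(length_ms = 128, step_ms = 50, fs_hz = 2000) {
  length_ms <- check_scalar_pos(length_ms, "length_ms")
  step_ms <- check_scalar_pos(step_ms, "step_ms")
  fs_hz <- check_scalar_pos(fs_hz, "fs_hz")
  if (step_ms > length_ms)
    stop_invalid("`step_ms` must not exceed `length_ms`")
  len_n <- length_ms * fs_hz / 1000
  step_n <- step_ms * fs_hz / 1000
  if (abs(len_n - round(len_n)) > 1e-8 || abs(step_n - round(step_n)) > 1e-8)
    stop_invalid("window and step must resolve to whole sample counts at %g Hz",
                 fs_hz)
  structure(list(length_ms = length_ms, step_ms = step_ms, fs_hz = fs_hz,
                 length_n = as.integer(round(len_n)),
                 step_n = as.integer(round(step_n))),
            class = "window_spec")
}

#' Hampel despiking filter
#'
#' Replaces samples that deviate from the local rolling median by more than
#' `n_sigmas` robust standard deviations (1.4826 x rolling MAD) with that
#' median; used to remove power-line and motion spikes. Windows are truncated
#' at the signal edges. A constant signal passes through unchanged (zero MAD
#' gives a zero threshold that is never strictly exceeded).
#'
#' @param x Numeric signal vector.
#' @param half_window Samples on each side of the rolling window (>= 1 and
#'   smaller than the signal length).
#' @param n_sigmas Outlier threshold in robust standard deviations.
#' @return Filtered signal of the same length.
#' @export
hampel_filter <- function(x, half_window = 5, n_sigmas = 3) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_invalid("`x` must be a finite numeric vector")
  half_window <- check_scalar_count(half_window, "half_window")
  if (half_window >= length(x))
    stop_invalid("`half_window` must be smaller than the signal length")
  n_sigmas <- check_scalar_pos(n_sigmas, "n_sigmas")
  .hampel_cpp(as.numeric(x), half_window, n_sigmas)
}

#' Zero-phase Butterworth band-pass
#'
#' Band-pass filters a signal with an order-`order` Butterworth design
#' applied forward and backward (`signal::filtfilt`), so the output has zero
#' phase shift and window labels are not displaced in time. Default band is
#' 30-400 Hz, the usual surface-EMG band.
#'
#' @param x Numeric signal vector.
#' @param fs_hz Sampling rate in Hz.
#' @param low_hz,high_hz Band corner frequencies; `0 < low < high < fs/2`.
#' @param order Butterworth design order.
#' @return Filtered signal of the same length.
#' @export
bandpass_filter <- function(x, fs_hz, low_hz = 30, high_hz = 400, order = 4) {
  fs_hz <- check_scalar_pos(fs_hz, "fs_hz")
  if (!is.finite(low_hz) || !is.finite(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz || high_hz >= fs_hz / 2)
    stop_invalid("corner frequencies must satisfy 0 < low < high < fs/2")
  order <- check_scalar_count(order, "order")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
  x <- as.numeric(x)
  n <- length(x)
  # odd (reflect-and-negate) extension suppresses the forward-backward edge
  # transient; a few time constants of the low corner is ample
  p <- min(n - 1L, ceiling(5 * fs_hz / low_hz))
  if (p < 1L) return(as.numeric(signal::filtfilt(bf, x)))
  ext <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  as.numeric(signal::filtfilt(bf, ext))[(p + 1L):(p + n)]
}

#' Band-limited up-sampling
#'
#' Raises the sampling rate by polyphase band-limited interpolation
#' (`signal::resample`); equal input and output rates return the input
#' unchanged. The output length is `round(length(x) * fs_out / fs_in)`.
#'
#' @param x Numeric signal vector.
#' @param fs_in,fs_out Input and output sampling rates; `fs_out >= fs_in`,
#'   both whole numbers of Hz.
#' @return The resampled signal.
#' @export
upsample_signal <- function(x, fs_in, fs_out) {
  fs_in <- check_scalar_pos(fs_in, "fs_in")
  fs_out <- check_scalar_pos(fs_out, "fs_out")
  if (fs_out < fs_in)
    stop_invalid("`fs_out` must be >= `fs_in` (up-sampling only)")
  if (fs_out == fs_in) return(as.numeric(x))
  if (abs(fs_in - round(fs_in)) > 1e-9 || abs(fs_out - round(fs_out)) > 1e-9)
    stop_invalid("sampling rates must be whole numbers of Hz")
  g <- gcd2(round(fs_out), round(fs_in))
  p <- round(fs_out) / g
  q <- round(fs_in) / g
  y <- as.numeric(signal::resample(as.numeric(x), p, q))
  target <- round(length(x) * fs_out / fs_in)
  if (length(y) >= target) y[seq_len(target)]
  else c(y, rep(y[length(y)], target - length(y)))
}

#' Condition a raw recording
#'
#' Applies the fixed conditioning chain to every channel: up-sample to
#' `fs_target`, Hampel despiking, then zero-phase Butterworth band-pass.
#' Per-sample labels are carried to the new rate by nearest-index mapping.
#'
#' @param rec An [emg_recording()].
#' @param fs_target Target sampling rate (default 2000 Hz).
#' @param hampel_half_window,hampel_n_sigmas Hampel parameters.
#' @param low_hz,high_hz,order Band-pass parameters.
#' @return A conditioned [emg_recording()] at `fs_target`.
#' @export
preprocess_recording <- function(rec, fs_target = 2000,
                                 hampel_half_window = 5, hampel_n_sigmas = 3,
                                 low_hz = 30, high_hz = 400, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  n_in <- ncol(rec$signal)
  if (fs_target != rec$fs_hz) {
    n_out <- round(n_in * fs_target / rec$fs_hz)
    idx <- pmin(pmax(1L, ceiling(seq_len(n_out) * rec$fs_hz / fs_target)), n_in)
    labels <- rec$labels[idx]
    sig <- matrix(0, nrow(rec$signal), n_out)
    for (ch in seq_len(nrow(rec$signal)))
      sig[ch, ] <- upsample_signal(rec$signal[ch, ], rec$fs_hz, fs_target)
  } else {
    labels <- rec$labels
    sig <- rec$signal
  }
  for (ch in seq_len(nrow(sig))) {
    y <- hampel_filter(sig[ch, ], hampel_half_window, hampel_n_sigmas)
    sig[ch, ] <- bandpass_filter(y, fs_target, low_hz, high_hz, order)
  }
  emg_recording(sig, fs_target, labels, rec$class_names, rec$session)
}

#' Waveform length of a window
#'
#' The cumulative absolute sample-to-sample difference
#' \eqn{\sum_i |w_{i+1} - w_i|}, the time-domain EMG feature used throughout
#' this package (one value per channel per window).
#'
#' @param w Numeric window of at least 2 samples.
#' @return Non-negative scalar.
#' @examples
#' waveform_length(c(0, 1, 0, 1))  # 3
#' @export
waveform_length <- function(w) {
  if (!is.numeric(w) || length(w) < 2L)
    stop_invalid("`w` must be a numeric window with at least 2 samples")
  if (any(!is.finite(w)))
    stop_invalid("`w` must be finite")
  sum(abs(diff(w)))
}

#' Extract waveform-length features from a recording
#'
#' Tiles the recording with sliding windows and computes the waveform length
#' of every channel in every window, yielding one feature row per window
#' (channel count = feature dimension). A window straddling a label change is
#' labeled by the class occupying the majority of its samples, ties broken
#' toward the class that appears earliest in the window; such transition
#' windows are retained by default.
#'
#' @param rec An [emg_recording()] (normally conditioned first with
#'   [preprocess_recording()]).
#' @param spec A [window_spec()]; its rate must equal the recording rate.
#' @param drop_transitions If `TRUE`, windows whose samples are not all of
#'   one class are discarded.
#' @return A [feature_pool()] with window provenance (`session`,
#'   `t_start_ms`).
#' @export
extract_features <- function(rec, spec = window_spec(fs_hz = rec$fs_hz),
                             drop_transitions = FALSE) {
  stopifnot(inherits(rec, "emg_recording"), inherits(spec, "window_spec"))
  if (spec$fs_hz != rec$fs_hz)
    stop_invalid("window spec resolved at %g Hz but recording is at %g Hz",
                 spec$fs_hz, rec$fs_hz)
  n <- ncol(rec$signal)
  win <- spec$length_n
  step <- spec$step_n
  if (n < win)
    stop_invalid("recording shorter than one window (%d < %d samples)", n, win)
  starts <- seq.int(1L, n - win + 1L, by = step)
  n_win <- length(starts)

  feats <- matrix(0, n_win, nrow(rec$signal))
  for (ch in seq_len(nrow(rec$signal))) {
    cs <- c(0, cumsum(abs(diff(rec$signal[ch, ]))))
    feats[, ch] <- cs[starts + win - 1L] - cs[starts]
  }
  colnames(feats) <- paste0("ch", seq_len(ncol(feats)), "_wl")

  n_classes <- length(rec$class_names)
  labels <- integer(n_win)
  pure <- logical(n_win)
  for (i in seq_len(n_win)) {
    lw <- rec$labels[starts[i]:(starts[i] + win - 1L)]
    counts <- tabulate(lw, nbins = n_classes)
    top <- which(counts == max(counts))
    if (length(top) > 1L) {
      # tie: the class appearing earliest in the window wins
      first_pos <- vapply(top, function(cl) which.max(lw == cl), integer(1))
      top <- top[which.min(first_pos)]
    }
    labels[i] <- top
    pure[i] <- counts[top] == win
  }
  keep <- if (drop_transitions) which(pure) else seq_len(n_win)
  feature_pool(feats[keep, , drop = FALSE], labels[keep], rec$class_names,
               session = rec$session,
               t_start_ms = (starts[keep] - 1L) / rec$fs_hz * 1000,
               window_id = keep)
}
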