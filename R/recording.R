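#' Multichannel EMG recording
#'
#' Container for a (possibly synthetic) multichannel sEMG recording: a
#' channels-by-samples signal matrix, its sampling rate, a per-sample class
#' annotation, the class dictionary, and a session tag.
#'
#' @param signal Numeric matrix, channels x samples.
#' @param fs_hz Sampling rate in Hz.
#' @param labels Integer vector of per-sample class ids (1-based indices into
#'   `class_names`), one per sample.
#' @param class_names Character vector of class labels.
#' @param session Session tag, typically `"T1"` or `"T2"`.
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, fs_hz, labels, class_names, session = "T1") {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || any(!is.finite(signal)))
    stop_invalid("`signal` must be a finite numeric matrix (channels x samples)")
  fs_hz <- check_scalar_pos(fs_hz, "fs_hz")
  labels <- as.integer(labels)
  if (length(labels) != ncol(signal))
    stop_invalid("`labels` must have one entry per sample (%d != %d)",
                 length(labels), ncol(signal))
  if (anyNA(labels) || any(labels < 1L) || any(labels > length(class_names)))
    stop_invalid("every label must index `class_names`")
  structure(
    list(signal = signal, fs_hz = fs_hz, labels = labels,
         class_names = as.character(class_names),
         session = as.character(session)[1L]),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$session, nrow(x$signal), ncol(x$signal), x$fs_hz,
              ncol(x$signal) / x$fs_hz))
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names))
  cat("  samples per class:\n")
  print(tab)
  invisible(x)
}

# run-length encode labels for the sidecar header
rle_labels <- function(labels) {
  r <- rle(as.integer(labels))
  list(lengths = r$lengths, values = r$values)
}

#' Write / read a recording
#'
#' A recording is stored as a channels-first little-endian float64 binary
#' array (`<path>.bin`) plus a sidecar JSON header (`<path>.json`) holding the
#' sampling rate, class names, session tag, matrix shape, and the per-sample
#' labels as a run-length encoding.
#'
#' @param rec An [emg_recording()].
#' @param path Path stem; `.bin` and `.json` are appended.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [emg_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  header <- list(
    format = "emgal-recording-v1",
    fs_hz = rec$fs_hz,
    n_channels = nrow(rec$signal),
    n_samples = ncol(rec$signal),
    class_names = rec$class_names,
    session = rec$session,
    labels_rle = rle_labels(rec$labels))
  jsonlite::write_json(header, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  # channels-first: channel 1's samples, then channel 2's, ...
  writeBin(as.numeric(t(rec$signal)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(header$format, "emgal-recording-v1"))
    stop_invalid("`%s.json` is not an emgal recording header", path)
  n_ch <- header$n_channels
  n_s <- header$n_samples
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n_ch * n_s, size = 8L, endian = "little")
  if (length(raw) != n_ch * n_s)
    stop_invalid("binary payload truncated: expected %d values, got %d",
                 n_ch * n_s, length(raw))
  signal <- t(matrix(raw, nrow = n_s, ncol = n_ch))
  labels <- rep(as.integer(header$labels_rle$values),
                times = header$labels_rle$lengths)
  emg_recording(signal, header$fs_hz, labels, header$class_names,
                header$session)
}
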