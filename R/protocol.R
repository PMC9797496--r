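#' Recording-session protocol
#'
#' Describes the cued grip protocol of one recording session: the ordered set
#' of movement classes (one of which is the rest class), how often each grip
#' is repeated, the duration of each muscle-activation and rest phase, the
#' number of sEMG channels, and the sampling rate.
#'
#' The default protocol is five grips plus rest, ten repetitions per grip,
#' 5 s of activation followed by 3 s of rest, 16 channels at 2 kHz.
#'
#' @param class_names Ordered character vector of class labels; must contain
#'   the label `"rest"` exactly once. All other entries are grip classes.
#' @param reps_per_grip Number of repetitions of each grip (>= 1).
#' @param active_s Seconds of muscle activation per repetition (> 0).
#' @param rest_s Seconds of rest following each activation (>= 0).
#' @param n_channels Number of sEMG channels (>= 1).
#' @param fs_hz Sampling rate in Hz.
#'
#' @return An object of class `session_protocol`.
#' @examples
#' p <- session_protocol()
#' p$reps_per_grip
#' @export
session_protocol <- function(class_names = c("rest", "power", "lateral",
                                             "tripod", "pointer", "open"),
                             reps_per_grip = 10,
                             active_s = 5,
                             rest_s = 3,
                             n_channels = 16,
                             fs_hz = 2000) {
  if (!is.character(class_names) || anyDuplicated(class_names))
    stop_invalid("`class_names` must be unique character labels")
  if (sum(class_names == "rest") != 1L)
    stop_invalid("`class_names` must contain exactly one \"rest\" label")
  if (length(class_names) < 2L)
    stop_invalid("at least one grip class is required besides rest")
  reps_per_grip <- check_scalar_count(reps_per_grip, "reps_per_grip")
  active_s <- check_scalar_pos(active_s, "active_s")
  rest_s <- check_scalar_pos(rest_s, "rest_s", strict = FALSE)
  n_channels <- check_scalar_count(n_channels, "n_channels")
  fs_hz <- check_scalar_pos(fs_hz, "fs_hz")
  structure(
    list(class_names = class_names, reps_per_grip = reps_per_grip,
         active_s = active_s, rest_s = rest_s,
         n_channels = n_channels, fs_hz = fs_hz),
    class = "session_protocol")
}

#' @export
print.session_protocol <- function(x, ...) {
  grips <- setdiff(x$class_names, "rest")
  cat("Session protocol:", length(grips), "grips + rest\n")
  cat("  grips:        ", paste(grips, collapse = ", "), "\n")
  cat(sprintf("  repetitions:   %d x (%g s active + %g s rest)\n",
              x$reps_per_grip, x$active_s, x$rest_s))
  cat(sprintf("  channels/rate: %d channels @ %g Hz\n", x$n_channels, x$fs_hz))
  invisible(x)
}

#' Between-session drift model
#'
#' Parameterizes the distribution shift applied when deriving a second-session
#' recording from a first-session one: per-class multiplicative amplitude
#' changes (electrode-skin impedance and muscle-state change), mixing between
#' adjacent channel pairs (electrode shift), and an additive noise offset.
#'
#' @param amplitude_scale Numeric vector of positive multiplicative factors,
#'   one per class (in protocol class order, rest included).
#' @param rotation_angle Radians of rotation mixing each adjacent channel pair
#'   `(1,2), (3,4), ...`; 0 leaves channels untouched.
#' @param noise_sd_delta Standard deviation of extra additive Gaussian noise.
#'
#' @return An object of class `drift_model`.
#' @seealso [apply_drift()], [default_drift()]
#' @export
drift_model <- function(amplitude_scale, rotation_angle = 0,
                        noise_sd_delta = 0) {
  if (!is.numeric(amplitude_scale) || any(!is.finite(amplitude_scale)) ||
      any(amplitude_scale <= 0))
    stop_invalid("`amplitude_scale` must be finite positive factors")
  if (length(rotation_angle) != 1L || !is.finite(rotation_angle))
    stop_invalid("`rotation_angle` must be a single finite number")
  noise_sd_delta <- check_scalar_pos(noise_sd_delta, "noise_sd_delta",
                                     strict = FALSE)
  structure(
    list(amplitude_scale = as.numeric(amplitude_scale),
         rotation_angle = as.numeric(rotation_angle),
         noise_sd_delta = noise_sd_delta),
    class = "drift_model")
}

#' Default mild drift for a given number of classes
#'
#' Draws per-class amplitude factors uniformly from `scale_range`
#' (default mild gains in \[0.75, 1.25\]) and combines them with a small
#' adjacent-channel rotation and a small additive-noise offset.
#'
#' @param n_classes Number of classes (rest included).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param scale_range Length-2 range for the amplitude factors.
#' @param rotation_angle Radians of adjacent-channel mixing.
#' @param noise_sd_delta Additive noise standard deviation.
#' @return A [drift_model()].
#' @export
default_drift <- function(n_classes, seed, scale_range = c(0.75, 1.25),
                          rotation_angle = 0.2, noise_sd_delta = 0.05) {
  n_classes <- check_scalar_count(n_classes, "n_classes")
  scales <- with_seed(seed,
                      runif(n_classes, scale_range[1L], scale_range[2L]))
  drift_model(scales, rotation_angle, noise_sd_delta)
}
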