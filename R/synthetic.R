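#' Generate a synthetic grip-protocol sEMG session
#'
#' Synthesizes a multichannel sEMG-like recording following a cued grip
#' protocol. Each channel carries unit-variance Gaussian noise band-limited
#' to 30-400 Hz, amplitude-modulated by the protocol: during a grip
#' repetition the envelope rises (100 ms linear ramp by default) to an
#' amplitude set by the grip's signal-to-noise level, a per-repetition gain
#' jitter, and a class-specific per-channel gain profile; between repetitions
#' the envelope falls back to the low rest amplitude. The per-channel gain
#' profiles are the simulated subject's spatial muscle signature and are
#' drawn from `profile_seed`, so two sessions of the same "subject" share
#' profiles while their noise realizations differ.
#'
#' @param protocol A [session_protocol()].
#' @param class_snr Positive amplitude of each grip class relative to the
#'   unit-variance noise carrier; one value per non-rest class.
#' @param seed Integer seed for the session's noise and gain jitter; the
#'   function is a pure function of its arguments including the seed.
#' @param profile_seed Seed for the subject's per-channel gain profiles
#'   (defaults to `seed`). Keep it fixed across the sessions of one subject.
#' @param rest_sd Envelope amplitude during rest (>= 0).
#' @param ramp_ms Linear onset/offset ramp between rest and grip, in ms.
#' @param trial_jitter_sd Log-scale standard deviation of the per-repetition
#'   multiplicative gain jitter (0 disables it).
#' @param envelope_noise_sd Log-scale standard deviation of a slow (about
#'   2 Hz band-limited) drive-intensity fluctuation shared across channels,
#'   emulating within-trial contraction-level variability (0 disables it).
#' @param fs_native Optional native sampling rate to synthesize at (for
#'   example 1111 Hz, to exercise the up-sampling path); default is the
#'   protocol rate.
#' @param session Session tag to store in the recording.
#'
#' @return An [emg_recording()].
#' @examples
#' p <- session_protocol(reps_per_grip = 1, active_s = 1, rest_s = 0.5,
#'                       n_channels = 4)
#' rec <- generate_session(p, seed = 1)
#' rec
#' @export
generate_session <- function(protocol,
                             class_snr = NULL,
                             seed = 1L,
                             profile_seed = seed,
                             rest_sd = 0.1,
                             ramp_ms = 100,
                             trial_jitter_sd = 0.35,
                             envelope_noise_sd = 0.45,
                             fs_native = NULL,
                             session = "T1") {
  stopifnot(inherits(protocol, "session_protocol"))
  grips <- setdiff(protocol$class_names, "rest")
  n_grips <- length(grips)
  if (is.null(class_snr)) class_snr <- rep(1, n_grips)
  if (length(class_snr) != n_grips || any(!is.finite(class_snr)) ||
      any(class_snr <= 0))
    stop_invalid("`class_snr` must hold one positive value per grip class (%d)",
                 n_grips)
  rest_sd <- check_scalar_pos(rest_sd, "rest_sd", strict = FALSE)
  ramp_ms <- check_scalar_pos(ramp_ms, "ramp_ms", strict = FALSE)
  trial_jitter_sd <- check_scalar_pos(trial_jitter_sd, "trial_jitter_sd",
                                      strict = FALSE)
  envelope_noise_sd <- check_scalar_pos(envelope_noise_sd,
                                        "envelope_noise_sd", strict = FALSE)

  fs <- if (is.null(fs_native)) protocol$fs_hz else
    check_scalar_pos(fs_native, "fs_native")
  active_n <- round(protocol$active_s * fs)
  rest_n <- round(protocol$rest_s * fs)
  ramp_n <- min(round(ramp_ms / 1000 * fs), floor(active_n / 2))
  rest_id <- which(protocol$class_names == "rest")
  grip_ids <- match(grips, protocol$class_names)

  # per-sample class labels: grip blocks of (active, rest) repetitions
  one_rep <- function(gid) c(rep(gid, active_n), rep(rest_id, rest_n))
  labels <- unlist(lapply(grip_ids, function(gid)
    rep(one_rep(gid), protocol$reps_per_grip)))
  n <- length(labels)
  grip_of_sample <- match(labels, grip_ids)     # NA during rest

  # subject signature: per-grip channel gain profiles, normalized to mean 1
  prof <- with_seed(profile_seed, {
    m <- matrix(runif(n_grips * protocol$n_channels, 0.85, 1.15),
                nrow = n_grips)
    m / rowMeans(m)
  })

  with_seed(seed, {
    jitter <- if (trial_jitter_sd > 0) {
      matrix(exp(rnorm(n_grips * protocol$reps_per_grip,
                       -trial_jitter_sd^2 / 2, trial_jitter_sd)),
             nrow = n_grips)
    } else matrix(1, n_grips, protocol$reps_per_grip)

    # scalar modulation g(t): 0 at rest, ramping to class_snr * jitter
    ramp_up <- if (ramp_n > 0) seq(0, 1, length.out = ramp_n) else numeric()
    plateau_n <- active_n - 2L * ramp_n
    shape <- c(ramp_up, rep(1, plateau_n), rev(ramp_up), rep(0, rest_n))
    g <- unlist(lapply(seq_len(n_grips), function(gi)
      unlist(lapply(seq_len(protocol$reps_per_grip), function(r)
        shape * (class_snr[gi] * jitter[gi, r])))))

    if (envelope_noise_sd > 0) {
      # slow drive-intensity fluctuation, shared across channels
      lp <- signal::butter(2, min(2 / (fs / 2), 0.99), type = "low")
      m <- as.numeric(signal::filtfilt(lp, rnorm(n)))
      m <- m / sd(m) * envelope_noise_sd
      g <- g * exp(m - envelope_noise_sd^2 / 2)
    }

    signal <- matrix(0, protocol$n_channels, n)
    for (ch in seq_len(protocol$n_channels)) {
      carrier <- bandpass_filter(rnorm(n), fs)
      carrier <- carrier / sd(carrier)
      pch <- c(0, prof[, ch])[ifelse(is.na(grip_of_sample), 0L,
                                     grip_of_sample) + 1L]
      signal[ch, ] <- (rest_sd + g * pch) * carrier
    }
    emg_recording(signal, fs, labels, protocol$class_names, session)
  })
}

#' Apply between-session drift to a recording
#'
#' Produces a second-session (`T2`) recording from a first-session one by
#' applying a [drift_model()]: samples of class `c` are scaled by
#' `amplitude_scale[c]`, adjacent channel pairs are mixed by a rotation of
#' `rotation_angle` radians, and Gaussian noise of sd `noise_sd_delta` is
#' added. The identity model (scales 1, angle 0, delta 0) returns the input
#' signal unchanged.
#'
#' @param rec An [emg_recording()].
#' @param drift A [drift_model()] with one amplitude factor per class.
#' @param seed Seed for the additive-noise draw.
#' @return An [emg_recording()] tagged `"T2"`.
#' @export
apply_drift <- function(rec, drift, seed = 1L) {
  stopifnot(inherits(rec, "emg_recording"), inherits(drift, "drift_model"))
  if (length(drift$amplitude_scale) != length(rec$class_names))
    stop_invalid("`amplitude_scale` must have one factor per class (%d)",
                 length(rec$class_names))
  sig <- rec$signal
  scale_vec <- drift$amplitude_scale[rec$labels]
  if (any(scale_vec != 1))
    sig <- sig * rep(scale_vec, each = nrow(sig))
  if (drift$rotation_angle != 0 && nrow(sig) >= 2L) {
    cs <- cos(drift$rotation_angle)
    sn <- sin(drift$rotation_angle)
    for (i in seq_len(floor(nrow(sig) / 2))) {
      a <- sig[2L * i - 1L, ]
      b <- sig[2L * i, ]
      sig[2L * i - 1L, ] <- cs * a - sn * b
      sig[2L * i, ] <- sn * a + cs * b
    }
  }
  if (drift$noise_sd_delta > 0)
    sig <- sig + with_seed(seed,
      matrix(rnorm(length(sig), 0, drift$noise_sd_delta), nrow(sig)))
  emg_recording(sig, rec$fs_hz, rec$labels, rec$class_names, session = "T2")
}

#' Generate a Gaussian feature-space pool
#'
#' Fast fixture bypassing signal synthesis: balanced Gaussian class clusters
#' with unit covariance and pairwise mean distance `class_separation`.
#'
#' @param n_classes Number of classes (first is named `"rest"`).
#' @param n_per_class Windows per class.
#' @param n_features Feature dimension (must be >= `n_classes` so the class
#'   means can sit on orthogonal axes).
#' @param class_separation Euclidean distance between any two class means.
#' @param seed Integer seed.
#' @param class_names Optional class labels; default grip names when
#'   `n_classes` is 6, generic names otherwise.
#' @return A [feature_pool()] with sequential window start times.
#' @export
generate_feature_pool <- function(n_classes, n_per_class, n_features,
                                  class_separation = 1, seed = 1L,
                                  class_names = NULL) {
  n_classes <- check_scalar_count(n_classes, "n_classes")
  n_per_class <- check_scalar_count(n_per_class, "n_per_class")
  n_features <- check_scalar_count(n_features, "n_features")
  if (!is.finite(class_separation) || class_separation < 0)
    stop_invalid("`class_separation` must be finite and non-negative")
  if (n_features < n_classes)
    stop_invalid("`n_features` must be >= `n_classes` for orthogonal means")
  if (is.null(class_names)) {
    class_names <- if (n_classes == 6L)
      c("rest", "power", "lateral", "tripod", "pointer", "open")
    else c("rest", paste0("grip", seq_len(n_classes - 1L)))[seq_len(n_classes)]
  }
  n <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes), each = n_per_class)
  means <- diag(n_classes) * class_separation / sqrt(2)
  means <- cbind(means, matrix(0, n_classes, n_features - n_classes))
  x <- with_seed(seed, matrix(rnorm(n * n_features), n, n_features))
  x <- x + means[labels, , drop = FALSE]
  colnames(x) <- paste0("f", seq_len(n_features))
  feature_pool(x, labels, class_names,
               t_start_ms = (seq_len(n) - 1) * 50)
}

#' Generate a drifted two-session subject
#'
#' Convenience wrapper producing the paired recordings of one simulated
#' subject: a `T1` session and a drifted `T2` session sharing the subject's
#' channel gain profiles but with independent noise realizations.
#'
#' @inheritParams generate_session
#' @param drift A [drift_model()]; default is [default_drift()] drawn from a
#'   seed derived from `seed`.
#' @param ... Further arguments passed to [generate_session()].
#' @return A list with elements `T1` and `T2` ([emg_recording()]s).
#' @export
generate_subject_sessions <- function(protocol, class_snr = NULL, seed = 1L,
                                      drift = NULL, ...) {
  sub <- with_seed(seed, sample.int(2147483646L, 4L))
  if (is.null(drift))
    drift <- default_drift(length(protocol$class_names), sub[4L])
  t1 <- generate_session(protocol, class_snr, seed = sub[1L],
                         profile_seed = sub[3L], session = "T1", ...)
  t2 <- generate_session(protocol, class_snr, seed = sub[2L],
                         profile_seed = sub[3L], session = "T2", ...)
  list(T1 = t1, T2 = apply_drift(t2, drift, seed = sub[2L]))
}
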