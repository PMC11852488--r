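# Synthetic multichannel EEG with controllable per-band spectral content and
# broadband complexity, standing in for real scalp recordings so that every
# downstream stage (filtering, epoching, feature extraction, classification)
# can be exercised and tested deterministically.

#' Canonical 14-channel montage
#'
#' Channel labels of the 14-electrode consumer EEG montage assumed throughout
#' the package, in canonical order.
#'
#' @return character vector of 14 channel labels.
#' @export
eeg_channels <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

# Frontal weighting used for injected ocular artifacts: blinks project
# strongly onto prefrontal electrodes and barely onto posterior ones.
blink_weights <- function() {
  w <- stats::setNames(rep(0.05, 14), eeg_channels())
  w[c("AF3", "AF4")] <- 1
  w[c("F7", "F8", "F3", "F4")] <- 0.8
  w[c("FC5", "FC6")] <- 0.4
  w
}

#' Emotion-state signal profile
#'
#' Describes the spectral and complexity signature of one synthetic emotional
#' state: a nonnegative amplitude per classical EEG band, a broadband-noise
#' mixing proportion (`complexity`, higher means more irregular signal and
#' higher sample entropy), and per-channel gains.
#'
#' The shipped profiles (see [default_profiles()]) are illustrative
#' constants, not claims about real emotion physiology.
#'
#' @param state_label one of `"neutral"`, `"fear"`, `"anger"`.
#' @param band_amplitudes named nonnegative numeric of length 5 with names
#'   `delta`, `theta`, `alpha`, `beta`, `gamma` (relative RMS weights).
#' @param complexity broadband white-noise mixing proportion in `[0, 1]`.
#' @param channel_gains numeric of length 14, per-channel multiplier.
#' @return an object of class `emotion_profile`.
#' @export
emotion_profile <- function(state_label,
                            band_amplitudes,
                            complexity,
                            channel_gains = rep(1, 14)) {
  state_label <- match.arg(state_label, c("neutral", "fear", "anger"))
  bands <- eeg_bands()$name
  if (is.null(names(band_amplitudes)) ||
      !setequal(names(band_amplitudes), bands)) {
    stop("`band_amplitudes` must be named with exactly: ",
         paste(bands, collapse = ", "), call. = FALSE)
  }
  band_amplitudes <- band_amplitudes[bands]
  if (any(!is.finite(band_amplitudes)) || any(band_amplitudes < 0)) {
    stop("`band_amplitudes` must be finite and >= 0", call. = FALSE)
  }
  stop_if_not_scalar_number(complexity, "complexity", lower = 0)
  if (complexity > 1) stop("`complexity` must be in [0, 1]", call. = FALSE)
  if (length(channel_gains) != 14L || any(!is.finite(channel_gains))) {
    stop("`channel_gains` must be 14 finite values", call. = FALSE)
  }
  structure(
    list(state_label = state_label,
         band_amplitudes = band_amplitudes,
         complexity = complexity,
         channel_gains = as.numeric(channel_gains)),
    class = "emotion_profile"
  )
}

#' Default per-state profiles
#'
#' Three shipped profiles differing in both band-amplitude pattern and
#' complexity: an alpha-dominant low-complexity neutral state, a
#' beta/gamma-weighted high-complexity fear state, and a delta/theta-weighted
#' intermediate-complexity anger state. The values are config-visible
#' constants chosen to give the three classes distinct, learnable signatures.
#'
#' @return named list of three [emotion_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    neutral = emotion_profile(
      "neutral",
      c(delta = 1.0, theta = 0.8, alpha = 3.0, beta = 0.7, gamma = 0.3),
      complexity = 0.15
    ),
    fear = emotion_profile(
      "fear",
      c(delta = 0.8, theta = 0.7, alpha = 0.8, beta = 2.5, gamma = 1.5),
      complexity = 0.60
    ),
    anger = emotion_profile(
      "anger",
      c(delta = 3.0, theta = 2.0, alpha = 0.7, beta = 1.0, gamma = 0.8),
      complexity = 0.35
    )
  )
}

#' Construct an EEG recording object
#'
#' @param samples channels x time numeric matrix, microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one per row of `samples`.
#' @param state_label emotion class label or `NA`.
#' @return an object of class `eeg_recording` with fields `samples`, `fs`,
#'   `channel_labels`, `state_label`, `duration`.
#' @export
eeg_recording <- function(samples, fs, channel_labels,
                          state_label = NA_character_) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channel_labels)) {
    stop("`samples` must have exactly one row per channel label",
         call. = FALSE)
  }
  stop_if_not_scalar_number(fs, "fs", lower = 0, strict = TRUE)
  if (any(!is.finite(samples))) {
    stop("`samples` must be all finite", call. = FALSE)
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels),
         state_label = state_label,
         duration = ncol(samples) / fs),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), state=%s\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$duration,
              x$state_label))
  invisible(x)
}

# Band-limit unit-variance white noise by zeroing FFT bins outside
# [f_lo, f_hi) (half-open, applied to |f|), then return the real part.
band_limited_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- ifelse(freq > fs / 2, freq - fs, freq)
  keep <- abs(freq) >= f_lo & abs(freq) < f_hi
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate a synthetic EEG recording
#'
#' Each channel is an independent mixture of per-band band-limited Gaussian
#' noise components (relative RMS per the profile's `band_amplitudes`) and
#' broadband white noise, mixed in proportion `complexity`:
#' `x = (1 - c) * structured + c * white`, both terms unit-RMS before mixing.
#' The result is scaled to a fixed per-channel RMS of 18 microvolts (typical
#' scalp-EEG peaks around +/-50-70 uV) and multiplied by the profile's
#' channel gains. Output is bit-reproducible for a fixed seed.
#'
#' @param profile an [emotion_profile()].
#' @param duration length in seconds (>= 1).
#' @param fs sampling rate, Hz; must be at least twice the highest band edge.
#' @param seed integer seed; all randomness flows from it.
#' @return an [eeg_recording()] with `state_label` from the profile.
#' @export
generate_recording <- function(profile, duration, fs = 128, seed = 1) {
  if (!inherits(profile, "emotion_profile")) {
    stop("`profile` must be an emotion_profile", call. = FALSE)
  }
  stop_if_not_scalar_number(duration, "duration", lower = 1)
  stop_if_not_scalar_number(fs, "fs", lower = 0, strict = TRUE)
  bands <- eeg_bands()
  if (fs < 2 * max(bands$f_hi)) {
    stop(sprintf("`fs` must be >= %g Hz (twice the highest band edge)",
                 2 * max(bands$f_hi)), call. = FALSE)
  }
  n <- round(duration * fs)
  target_rms <- 18  # microvolts; see methods vignette
  amps <- profile$band_amplitudes
  cplx <- profile$complexity
  samples <- with_seed(seed, {
    out <- matrix(0, nrow = 14, ncol = n)
    for (ch in seq_len(14)) {
      structured <- numeric(n)
      if (any(amps > 0)) {
        for (b in seq_len(nrow(bands))) {
          if (amps[[bands$name[b]]] > 0) {
            comp <- band_limited_noise(n, fs, bands$f_lo[b], bands$f_hi[b])
            structured <- structured +
              amps[[bands$name[b]]] * comp / rms(comp)
          }
        }
        structured <- structured / rms(structured)
      }
      broad <- stats::rnorm(n)
      broad <- broad / rms(broad)
      x <- (1 - cplx) * structured + cplx * broad
      if (rms(x) > 0) x <- x / rms(x) * target_rms
      out[ch, ] <- x * profile$channel_gains[ch]
    }
    out
  })
  eeg_recording(samples, fs, eeg_channels(), profile$state_label)
}

#' Inject ocular and power-line artifacts
#'
#' Adds frontal-weighted Gaussian-shaped transient deflections ("blinks") at
#' randomly scheduled times plus a pure sinusoid at `line_freq` on all
#' channels. The number of blinks is `round(blink_rate * duration / 60)`;
#' their times are returned so that rejection stages can be audited against
#' the known schedule.
#'
#' @param rec an [eeg_recording()].
#' @param blink_rate events per minute (>= 0).
#' @param blink_amplitude peak deflection in microvolts (>= 0).
#' @param line_freq power-line frequency in Hz (must be `< fs/2`).
#' @param line_amplitude sinusoid amplitude in microvolts (>= 0).
#' @param seed integer seed for blink scheduling.
#' @return list with `recording` (new [eeg_recording()]) and `blink_times`
#'   (numeric vector of blink-center times in seconds).
#' @export
inject_artifacts <- function(rec, blink_rate = 0, blink_amplitude = 400,
                             line_freq = 50, line_amplitude = 0, seed = 1) {
  if (!inherits(rec, "eeg_recording")) {
    stop("`rec` must be an eeg_recording", call. = FALSE)
  }
  for (nm in c("blink_rate", "blink_amplitude", "line_amplitude")) {
    stop_if_not_scalar_number(get(nm), nm, lower = 0)
  }
  if (line_freq >= rec$fs / 2) {
    stop(sprintf("`line_freq` (%g Hz) must be below the Nyquist frequency %g Hz",
                 line_freq, rec$fs / 2), call. = FALSE)
  }
  n <- ncol(rec$samples)
  tvec <- (seq_len(n) - 1) / rec$fs
  samples <- rec$samples
  n_blinks <- round(blink_rate * rec$duration / 60)
  blink_times <- numeric(0)
  if (n_blinks > 0 && blink_amplitude > 0) {
    margin <- min(0.3, rec$duration / 4)
    blink_times <- with_seed(seed, {
      sort(stats::runif(n_blinks, margin, rec$duration - margin))
    })
    w <- blink_weights()[rec$channel_labels]
    w[is.na(w)] <- 0.05
    blink_sd <- 0.06  # seconds; ~0.3 s visible blink width
    for (t0 in blink_times) {
      idx <- which(abs(tvec - t0) <= 4 * blink_sd)
      kern <- blink_amplitude * exp(-(tvec[idx] - t0)^2 / (2 * blink_sd^2))
      samples[, idx] <- samples[, idx] + outer(w, kern)
    }
  }
  if (line_amplitude > 0) {
    line <- line_amplitude * sin(2 * pi * line_freq * tvec)
    samples <- sweep(samples, 2, line, "+")
  }
  list(
    recording = eeg_recording(samples, rec$fs, rec$channel_labels,
                              rec$state_label),
    blink_times = blink_times
  )
}
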