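# Nonlinear-complexity (sample entropy) and spectral (band power spectral
# density) features, assembled into per-epoch feature matrices.

#' Canonical EEG frequency bands
#'
#' Default analysis bands: delta 1-4, theta 4-8, alpha 8-13, beta 13-30,
#' gamma 31-47 Hz. Intervals are half-open `[f_lo, f_hi)`, so 4 Hz belongs
#' to theta, not delta; the 30-31 Hz gap between beta and gamma is kept as
#' conventionally printed.
#'
#' @return data.frame with columns `name`, `f_lo`, `f_hi`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(1, 4, 8, 13, 31),
    f_hi = c(4, 8, 13, 30, 47),
    stringsAsFactors = FALSE
  )
}

#' Frequency-band definition
#'
#' Either pick a canonical band by name or give custom half-open edges.
#'
#' @param name band name; one of the [eeg_bands()] names (or any string when
#'   custom edges are supplied).
#' @param f_lo,f_hi optional custom edges in Hz, `0 < f_lo < f_hi`.
#' @return object of class `band_definition` with `name`, `f_lo`, `f_hi`.
#' @export
band_definition <- function(name, f_lo = NULL, f_hi = NULL) {
  if (is.null(f_lo) != is.null(f_hi)) {
    stop("give both `f_lo` and `f_hi`, or neither", call. = FALSE)
  }
  if (is.null(f_lo)) {
    bands <- eeg_bands()
    i <- match(name, bands$name)
    if (is.na(i)) {
      stop("unknown band name '", name, "'; known bands: ",
           paste(bands$name, collapse = ", "), call. = FALSE)
    }
    f_lo <- bands$f_lo[i]
    f_hi <- bands$f_hi[i]
  }
  stop_if_not_scalar_number(f_lo, "f_lo", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(f_hi, "f_hi", lower = 0, strict = TRUE)
  if (f_lo >= f_hi) stop("`f_lo` must be < `f_hi`", call. = FALSE)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

as_band <- function(band) {
  if (inherits(band, "band_definition")) band else band_definition(band)
}

#' Sample entropy parameters
#'
#' @param m embedding dimension (positive integer, default 2).
#' @param r match tolerance as a fraction of the series standard deviation
#'   (default 0.2).
#' @return object of class `sampen_params`.
#' @export
sampen_params <- function(m = 2, r = 0.2) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  stop_if_not_scalar_number(r, "r", lower = 0, strict = TRUE)
  structure(list(m = as.integer(m), r = r), class = "sampen_params")
}

#' Sample entropy of a time series
#'
#' `SampEn(m, r, N) = -ln(A / B)` where `B` counts pairs of length-`m`
#' templates within Chebyshev distance `r_abs` of each other, and `A` the
#' corresponding count for length-`m + 1` templates. Both counts run over
#' the first `N - m` templates, self-matches excluded and each unordered
#' pair counted once (the standard estimator). The tolerance is
#' `r * sd(series)` unless an absolute tolerance is given; for a constant
#' series the tolerance collapses to 0 but every template still matches
#' every other, so the value is 0 by convention.
#'
#' @param series numeric vector, length `N > m + 1`.
#' @param m embedding dimension (default 2).
#' @param r tolerance as a fraction of `sd(series)` (default 0.2).
#' @param r_absolute optional absolute tolerance overriding `r * sd`.
#' @return nonnegative entropy value; `Inf` (with a warning) when no
#'   length-`m + 1` templates match.
#' @export
sample_entropy <- function(series, m = 2, r = 0.2, r_absolute = NULL) {
  p <- sampen_params(m, r)
  series <- as.numeric(series)
  N <- length(series)
  if (any(!is.finite(series))) {
    stop("`series` must be all finite", call. = FALSE)
  }
  if (N <= p$m + 1) {
    stop(sprintf("series length (%d) must exceed m + 1 = %d", N, p$m + 1),
         call. = FALSE)
  }
  tol <- if (!is.null(r_absolute)) {
    stop_if_not_scalar_number(r_absolute, "r_absolute", lower = 0)
    r_absolute
  } else {
    p$r * stats::sd(series)
  }
  nt <- N - p$m
  emb <- function(len) {
    vapply(0:(len - 1), function(j) series[(1 + j):(nt + j)], numeric(nt))
  }
  Xm <- emb(p$m)
  Xm1 <- emb(p$m + 1)
  B <- sum(stats::dist(Xm, method = "maximum") <= tol)
  if (B == 0) {
    stop("undefined sample entropy: no template matches of length m",
         call. = FALSE)
  }
  A <- sum(stats::dist(Xm1, method = "maximum") <= tol)
  if (A == 0) {
    warning("no template matches of length m + 1; sample entropy is Inf")
    return(Inf)
  }
  -log(A / B)
}

#' One-sided periodogram power spectral density
#'
#' Raw (single-window, untapered) periodogram scaled so that
#' `sum(power) * df` equals the time-domain mean square (Parseval).
#' Optionally Welch-averaged over 50%-overlapping Hamming-windowed
#' segments.
#'
#' @param series numeric vector of length >= 2.
#' @param fs sampling rate, Hz.
#' @param method `"periodogram"` (default) or `"welch"`.
#' @param segment_length Welch segment length in samples (default
#'   `min(256, length(series))`).
#' @return data.frame with columns `freq` (Hz) and `power` (input units
#'   squared per Hz).
#' @export
periodogram_psd <- function(series, fs,
                            method = c("periodogram", "welch"),
                            segment_length = NULL) {
  method <- match.arg(method)
  series <- as.numeric(series)
  if (length(series) < 2L) stop("`series` must have length >= 2", call. = FALSE)
  stop_if_not_scalar_number(fs, "fs", lower = 0, strict = TRUE)
  one_sided <- function(x, w = NULL) {
    n <- length(x)
    if (is.null(w)) w <- rep(1, n)
    X <- stats::fft(x * w)
    # two-sided density |X|^2 / (fs * sum(w^2)); fold onto [0, fs/2]
    p2 <- Mod(X)^2 / (fs * sum(w^2))
    half <- floor(n / 2) + 1L
    p1 <- p2[seq_len(half)]
    if (n %% 2 == 0) {
      if (half > 2) p1[2:(half - 1)] <- 2 * p1[2:(half - 1)]
    } else {
      if (half > 1) p1[2:half] <- 2 * p1[2:half]
    }
    list(freq = (seq_len(half) - 1) * fs / n, power = p1)
  }
  if (method == "periodogram") {
    res <- one_sided(series)
  } else {
    n <- length(series)
    if (is.null(segment_length)) segment_length <- min(256L, n)
    segment_length <- as.integer(segment_length)
    step <- max(1L, segment_length %/% 2L)
    starts <- seq(1L, n - segment_length + 1L, by = step)
    w <- signal::hamming(segment_length)
    acc <- NULL
    for (s in starts) {
      seg <- series[s:(s + segment_length - 1L)]
      r <- one_sided(seg - mean(seg), w)
      acc <- if (is.null(acc)) r$power else acc + r$power
    }
    res <- list(freq = (seq_along(acc) - 1) * fs / segment_length,
                power = acc / length(starts))
  }
  data.frame(freq = res$freq, power = res$power)
}

#' Band power from the periodogram
#'
#' Integrates the one-sided periodogram over the half-open band
#' `[f_lo, f_hi)`: `sum(power * df)` over the bins in range. Deterministic;
#' units are the squared input amplitude.
#'
#' @param series numeric vector of length >= 2.
#' @param fs sampling rate, Hz.
#' @param band a [band_definition()] or canonical band name; must lie in
#'   `(0, fs/2)`.
#' @param method passed to [periodogram_psd()].
#' @return nonnegative band power.
#' @export
band_psd <- function(series, fs, band, method = "periodogram") {
  band <- as_band(band)
  if (band$f_hi > fs / 2) {
    stop(sprintf("band '%s' [%g, %g) exceeds the Nyquist frequency %g Hz",
                 band$name, band$f_lo, band$f_hi, fs / 2), call. = FALSE)
  }
  psd <- periodogram_psd(series, fs, method)
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= band$f_lo & psd$freq < band$f_hi
  if (!any(sel)) {
    stop(sprintf(
      "band '%s' [%g, %g) contains no frequency bins at fs = %g Hz (N = %d)",
      band$name, band$f_lo, band$f_hi, fs, length(series)), call. = FALSE)
  }
  sum(psd$power[sel]) * df
}

#' Per-epoch sample entropy on selected channels
#'
#' @param epochs an [epoch_set()].
#' @param channels channel labels to use.
#' @param m,r sample-entropy parameters.
#' @return epochs x channels numeric matrix.
#' @export
epoch_sampen <- function(epochs, channels = c("T7", "T8"), m = 2, r = 0.2) {
  check_channels(epochs, channels)
  out <- vapply(epochs$epochs, function(e) {
    vapply(channels, function(ch) {
      sample_entropy(e[match(ch, epochs$channel_labels), ], m = m, r = r)
    }, numeric(1))
  }, numeric(length(channels)))
  out <- if (length(channels) == 1L) matrix(out, ncol = 1) else t(out)
  colnames(out) <- paste0("sampen_", channels)
  out
}

check_channels <- function(epochs, channels) {
  if (length(channels) < 1L) {
    stop("at least one channel must be selected", call. = FALSE)
  }
  missing <- setdiff(channels, epochs$channel_labels)
  if (length(missing) > 0) {
    stop("unknown channel(s) ", paste(missing, collapse = ", "),
         "; available: ", paste(epochs$channel_labels, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble the per-band feature matrix
#'
#' One row per epoch; columns are the sample entropy of each selected
#' channel followed by the band power of each selected channel
#' (`sampen_<ch>..., psd_<band>_<ch>...`). Class labels are copied from the
#' epoch set.
#'
#' @param epochs an [epoch_set()].
#' @param channels channel labels (default `c("T7", "T8")`, the temporal
#'   pair used for classification).
#' @param band a [band_definition()] or canonical band name.
#' @param m,r sample-entropy parameters.
#' @param sampen optional precomputed matrix from [epoch_sampen()] (the
#'   entropy features do not depend on the analysis band, so callers looping
#'   over bands can compute them once).
#' @return object of class `feature_matrix`: list with `features` (numeric
#'   matrix), `labels` (character), `band`, `channels`.
#' @export
build_feature_matrix <- function(epochs, channels = c("T7", "T8"),
                                 band = "delta", m = 2, r = 0.2,
                                 sampen = NULL) {
  if (!inherits(epochs, "epoch_set")) {
    stop("`epochs` must be an epoch_set", call. = FALSE)
  }
  band <- as_band(band)
  check_channels(epochs, channels)
  if (is.null(sampen)) sampen <- epoch_sampen(epochs, channels, m, r)
  psd <- vapply(epochs$epochs, function(e) {
    vapply(channels, function(ch) {
      band_psd(e[match(ch, epochs$channel_labels), ], epochs$fs, band)
    }, numeric(1))
  }, numeric(length(channels)))
  psd <- if (length(channels) == 1L) matrix(psd, ncol = 1) else t(psd)
  colnames(psd) <- paste0("psd_", band$name, "_", channels)
  features <- cbind(sampen, psd)
  if (any(!is.finite(features))) {
    stop("non-finite feature values; check epoch content and parameters",
         call. = FALSE)
  }
  structure(
    list(features = features, labels = epochs$labels, band = band,
         channels = channels),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (band %s)\n",
              nrow(x$features), ncol(x$features), x$band$name))
  invisible(x)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  out <- as.data.frame(x$features)
  out$label <- x$labels
  out
}
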