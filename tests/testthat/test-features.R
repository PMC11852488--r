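test_that("sample entropy matches the exhaustive template-counting oracle", {
  # constant series: every template matches every other, A = B, SampEn 0
  expect_identical(sample_entropy(rep(5, 50), m = 2, r = 0.2), 0)

  # short periodic pattern with an absolute tolerance
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  expect_equal(sample_entropy(x, m = 2, r_absolute = 0.5),
               sampen_oracle(x, m = 2, tol = 0.5), tolerance = 1e-12)

  # random series across m (skipping draws where the estimator is undefined)
  set.seed(101)
  checked <- 0
  while (checked < 30) {
    n <- sample(20:64, 1)
    m <- sample(1:3, 1)
    y <- rnorm(n)
    expected <- sampen_oracle(y, m, 0.2 * sd(y))
    if (is.na(expected) || !is.finite(expected)) next
    expect_equal(sample_entropy(y, m = m, r = 0.2), expected,
                 tolerance = 1e-10)
    checked <- checked + 1
  }
})

test_that("white noise is more entropic than a sine of the same length", {
  set.seed(7)
  noise <- rnorm(256)
  t <- (0:255) / 256
  sine <- sin(2 * pi * 8 * t)
  se_noise <- sample_entropy(noise, m = 2, r = 0.2)
  se_sine <- sample_entropy(sine, m = 2, r = 0.2)
  expect_equal(se_noise, sampen_oracle(noise, 2, 0.2 * sd(noise)),
               tolerance = 1e-10)
  expect_equal(se_sine, sampen_oracle(sine, 2, 0.2 * sd(sine)),
               tolerance = 1e-10)
  expect_gt(se_noise, se_sine)
})

test_that("tightening the tolerance raises sample entropy on average", {
  # the finite-sample estimator is not strictly monotone in r on every
  # series (both match counts shrink together), but tighter tolerances
  # raise the estimate on average and it stays nonnegative throughout
  set.seed(11)
  checked <- 0
  deltas <- numeric(0)
  while (checked < 20) {
    y <- rnorm(64)
    wide <- sampen_oracle(y, 2, 0.5 * sd(y))
    tight <- sampen_oracle(y, 2, 0.25 * sd(y))
    if (anyNA(c(wide, tight)) || any(!is.finite(c(wide, tight)))) next
    vals <- c(sample_entropy(y, m = 2, r = 0.5),
              sample_entropy(y, m = 2, r = 0.25))
    expect_equal(vals, c(wide, tight), tolerance = 1e-10)
    expect_true(all(vals >= 0))
    deltas <- c(deltas, vals[2] - vals[1])
    checked <- checked + 1
  }
  expect_gt(mean(deltas), 0)
})

test_that("sample entropy rejects degenerate inputs", {
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "length")
  expect_error(sample_entropy(rnorm(50), m = 0), "positive integer")
  # widely spaced values with a tiny tolerance: no m-length matches at all
  expect_error(sample_entropy(2^(1:20), m = 2, r_absolute = 1e-6),
               "undefined")
})

test_that("band power integrates the periodogram correctly", {
  fs <- 128
  # zero signal -> zero power everywhere
  for (b in eeg_bands()$name) {
    expect_identical(band_psd(rep(0, 128), fs, b), 0)
  }
  # bin-aligned 10 Hz unit sine: virtually all power in alpha
  t <- (0:127) / fs
  s <- sin(2 * pi * 10 * t)
  alpha <- band_psd(s, fs, "alpha")
  total <- band_psd(s, fs, band_definition("broad", 0.5, 64))
  expect_gt(alpha / total, 0.95)
  expect_equal(total, 0.5, tolerance = 1e-9)  # mean square of a unit sine
  # Parseval: sum(power) * df == mean square
  set.seed(3)
  x <- rnorm(512)
  psd <- periodogram_psd(x, fs)
  df <- psd$freq[2] - psd$freq[1]
  expect_equal(sum(psd$power) * df, mean(x^2), tolerance = 1e-6)
  # additivity over adjacent half-open bands
  lo <- band_psd(x, fs, band_definition("lo", 2, 9.5))
  hi <- band_psd(x, fs, band_definition("hi", 9.5, 20))
  both <- band_psd(x, fs, band_definition("both", 2, 20))
  expect_equal(lo + hi, both, tolerance = 1e-10)
  # empty band errors with the band name
  expect_error(band_psd(rnorm(16), 128, band_definition("sliver", 1, 2)),
               "sliver")
  expect_error(band_psd(rnorm(128), 64, "gamma"), "Nyquist")
})

test_that("Welch averaging estimates the same spectrum level", {
  set.seed(5)
  x <- rnorm(4096)
  w <- periodogram_psd(x, 128, method = "welch", segment_length = 256)
  df <- w$freq[2] - w$freq[1]
  expect_equal(sum(w$power) * df, mean(x^2), tolerance = 0.1)
})

test_that("the feature matrix has one row per epoch and 4 documented columns", {
  rec <- generate_recording(default_profiles()$fear, 216, 128, seed = 6)
  es <- segment_epochs(rec, 1)
  fm <- build_feature_matrix(es, c("T7", "T8"), "delta")
  expect_equal(dim(fm$features), c(216L, 4L))
  expect_identical(colnames(fm$features),
                   c("sampen_T7", "sampen_T8", "psd_delta_T7", "psd_delta_T8"))
  expect_identical(fm$labels, rep("fear", 216))
  expect_true(all(is.finite(fm$features)))
})

test_that("feature extraction is deterministic and validates channels", {
  set.seed(8)
  e <- matrix(rnorm(2 * 128), 2, 128)
  es <- toy_epoch_set(list(e, e), labels = c("fear", "fear"))
  fm <- build_feature_matrix(es, c("T7", "T8"), "alpha")
  expect_identical(fm$features[1, ], fm$features[2, ])
  expect_error(build_feature_matrix(es, character(0), "alpha"),
               "at least one channel")
  expect_error(build_feature_matrix(es, "Cz", "alpha"), "available: T7, T8")
  expect_error(build_feature_matrix(es, "T7", "mu"), "unknown band")
})
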