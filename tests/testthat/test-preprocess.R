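test_that("baseline correction removes per-channel means and nothing else", {
  fs <- 128
  t <- (0:(5 * fs - 1)) / fs
  rec <- eeg_recording(rbind(rep(12, length(t)),
                             sin(2 * pi * 5 * t),
                             sin(2 * pi * 5 * t) + 3),
                       fs, c("T7", "T8", "O1"))
  out <- baseline_correct(rec)
  expect_true(all(abs(out$samples[1, ]) < 1e-12))
  expect_equal(out$samples[2, ], rec$samples[2, ] - mean(rec$samples[2, ]),
               tolerance = 1e-12)
  expect_lt(abs(mean(out$samples[3, ])), 1e-9)
  expect_equal(out$samples[3, ], rec$samples[3, ] - mean(rec$samples[3, ]),
               tolerance = 1e-12)
  expect_error(baseline_correct(eeg_recording(matrix(0, 1, 0), 128, "T7")),
               "empty")
})

test_that("band-pass kills DC, passes 10 Hz, and stops 70 Hz", {
  fs <- 128
  n <- 60 * fs
  t <- (0:(n - 1)) / fs
  ntaps <- 845  # 3.3 * fs / 0.5 Hz transition, rounded odd
  core <- (ntaps + 1):(n - ntaps)
  dc <- bandpass_filter(one_channel_rec(rep(1, n), fs))
  expect_lt(mean(abs(dc$samples[1, core])), 1e-3)
  s10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_filter(one_channel_rec(s10, fs))$samples[1, ]
  expect_lt(abs(sqrt(mean(y10[core]^2)) / sqrt(mean(s10[core]^2)) - 1), 0.05)
  fs2 <- 256
  n2 <- 60 * fs2
  t2 <- (0:(n2 - 1)) / fs2
  core2 <- (2 * ntaps + 1):(n2 - 2 * ntaps)
  s70 <- sin(2 * pi * 70 * t2)
  y70 <- bandpass_filter(one_channel_rec(s70, fs2))$samples[1, ]
  atten_db <- -20 * log10(sqrt(mean(y70[core2]^2)) / sqrt(mean(s70[core2]^2)))
  expect_gt(atten_db, 20)
  expect_error(bandpass_filter(one_channel_rec(rep(0, n), fs),
                               filter_spec(f_hi = 64)),
               "Nyquist")
})

test_that("notch removes the line frequency and spares the rest", {
  fs <- 128
  n <- 30 * fs
  t <- (0:(n - 1)) / fs
  core <- 1000:(n - 1000)
  s50 <- sin(2 * pi * 50 * t)
  y50 <- notch_filter(one_channel_rec(s50, fs), 50, 2)$samples[1, ]
  expect_lt(sqrt(mean(y50[core]^2)), 0.1 * sqrt(mean(s50[core]^2)))
  s10 <- sin(2 * pi * 10 * t)
  y10 <- notch_filter(one_channel_rec(s10, fs), 50, 2)$samples[1, ]
  expect_lt(abs(sqrt(mean(y10[core]^2)) / sqrt(mean(s10[core]^2)) - 1), 0.05)
  z <- notch_filter(one_channel_rec(rep(0, n), fs), 50, 2)
  expect_true(all(z$samples == 0))
  expect_error(notch_filter(one_channel_rec(s10, fs), 50, 0), "bandwidth")
  expect_error(notch_filter(one_channel_rec(s10, fs), 70, 2), "Nyquist")
})

test_that("filtering is linear", {
  fs <- 128
  n <- 30 * fs
  set.seed(42)
  x <- rnorm(n)
  y <- rnorm(n)
  a <- 2.5
  b <- -1.3
  f <- function(v) bandpass_filter(one_channel_rec(v, fs))$samples[1, ]
  lhs <- f(a * x + b * y)
  rhs <- a * f(x) + b * f(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
  g <- function(v) notch_filter(one_channel_rec(v, fs))$samples[1, ]
  expect_lt(max(abs(g(a * x + b * y) - (a * g(x) + b * g(y)))) /
              max(abs(g(x))), 1e-8)
})

test_that("fixed-window epoching counts windows and drops the tail", {
  rec216 <- generate_recording(default_profiles()$neutral, 216, 128, seed = 1)
  es <- segment_epochs(rec216, 1)
  expect_length(es$epochs, 216)
  expect_equal(dim(es$epochs[[1]]), c(14L, 128L))
  expect_true(all(es$labels == "neutral"))
  rec <- one_channel_rec(rnorm(round(10.5 * 128)), 128)
  es2 <- segment_epochs(rec, 1)
  expect_length(es2$epochs, 10)
  expect_error(segment_epochs(one_channel_rec(rnorm(64), 128), 1), "shorter")
  # conservation: n_epochs * window <= recording < (n_epochs + 1) * window
  for (dur in c(3.2, 7.9, 12.01)) {
    n <- round(dur * 128)
    k <- length(segment_epochs(one_channel_rec(rnorm(n), 128), 1)$epochs)
    expect_true(k * 128 <= n && n < (k + 1) * 128)
  }
})

test_that("threshold rejection keeps clean epochs and drops blink epochs", {
  clean <- generate_recording(default_profiles()$neutral, 60, 128, seed = 9)
  es <- segment_epochs(clean, 1)
  kept <- reject_artifact_epochs(es, amplitude_limit = 100)
  expect_length(kept$epochs, 60)
  expect_true(all(!attr(kept, "rejection")$rejected))

  # blinks on a silent background: the rejected set is exactly the epochs
  # where the (frontal, AF3) blink kernel exceeds the limit
  silent <- generate_recording(
    emotion_profile("neutral", c(delta = 0, theta = 0, alpha = 0, beta = 0,
                                 gamma = 0), 0),
    120, 128, seed = 1)
  inj <- inject_artifacts(silent, blink_rate = 6, blink_amplitude = 400,
                          line_amplitude = 0, seed = 13)
  es2 <- segment_epochs(inj$recording, 1)
  out <- reject_artifact_epochs(es2, amplitude_limit = 100)
  tvec <- (0:(120 * 128 - 1)) / 128
  amp <- rep(0, length(tvec))
  for (t0 in inj$blink_times) {
    idx <- abs(tvec - t0) <= 4 * 0.06
    amp[idx] <- amp[idx] + 400 * exp(-(tvec[idx] - t0)^2 / (2 * 0.06^2))
  }
  expected <- which(vapply(seq_len(120), function(e) {
    any(amp[((e - 1) * 128 + 1):(e * 128)] > 100)
  }, logical(1)))
  expect_identical(which(attr(out, "rejection")$rejected), expected)
  expect_error(reject_artifact_epochs(es, amplitude_limit = 0.001),
               "all epochs rejected")
})

test_that("the conditioning pipeline is a pure function of its inputs", {
  rec <- generate_recording(default_profiles()$anger, 30, 128, seed = 21)
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec)
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$labels, b$labels)
})
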