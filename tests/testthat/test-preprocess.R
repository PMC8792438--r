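test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  rec <- toneRecording(10, fs = 200, seconds = 60)
  rms <- function(x) sqrt(mean(x^2))
  inBand <- bandpassFilter(rec, list(lowHz = 8, highHz = 14))
  expect_lt(abs(rms(inBand@signal) - rms(rec@signal)) / rms(rec@signal), 0.05)
  outBand <- bandpassFilter(rec, list(lowHz = 31, highHz = 50))
  expect_lt(rms(outBand@signal) / rms(rec@signal), 0.02)

  zero <- eegRecording(matrix(0, 1, 2000), 200)
  expect_equal(bandpassFilter(zero, list(lowHz = 8, highHz = 14))@signal,
               zero@signal)
})

test_that("band-pass validates band limits and signal length", {
  rec <- toneRecording(10, fs = 80, seconds = 10)
  expect_error(bandpassFilter(rec, list(lowHz = 31, highHz = 50)),
               class = "msmra_invalid_band")
  short <- eegRecording(matrix(rnorm(10), 1, 10), 200)
  expect_error(bandpassFilter(short, list(lowHz = 8, highHz = 14)),
               class = "msmra_too_short")
})

test_that("window DE matches the Gaussian closed form", {
  set.seed(101)
  x <- rnorm(1e5)
  expect_equal(computeDEWindow(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.02)
  ## scaling by a shifts DE by exactly log(a)
  expect_equal(computeDEWindow(2 * x) - computeDEWindow(x), log(2),
               tolerance = 1e-9)
  y <- rnorm(1e5, sd = 3)
  expect_equal(computeDEWindow(y), 0.5 * log(2 * pi * exp(1)) + log(3),
               tolerance = 0.02)
  expect_error(computeDEWindow(rep(1, 100)),
               class = "msmra_degenerate_window")
  expect_error(computeDEWindow(1), class = "msmra_degenerate_window")
})

test_that("DE estimator is consistent on simulated Gaussian windows", {
  set.seed(202)
  errs <- replicate(100, {
    abs(computeDEWindow(rnorm(1e4, sd = 1.7)) -
          0.5 * log(2 * pi * exp(1) * 1.7^2))
  })
  expect_gt(mean(errs < 0.05), 0.99)
})

test_that("feature extraction has the right geometry and labels", {
  set.seed(11)
  rec <- eegRecording(matrix(rnorm(3 * 2000), 3, 2000), 200,
                      trials = rbind(c(1, 1001), c(1001, 2001)),
                      labels = c(0L, 2L))
  ft <- extractDEFeatures(rec, windowS = 1)
  expect_s4_class(ft, "FeatureTensor")
  expect_equal(dim(featureValues(ft)), c(10L, 15L))  # channels x bands
  expect_equal(windowLabels(ft), rep(c(0L, 2L), each = 5L))

  ## one 10 s trial at fs 200 and 1 s windows -> 10 windows
  rec1 <- eegRecording(matrix(rnorm(2000), 1, 2000), 200)
  expect_equal(nWindows(extractDEFeatures(rec1)), 10L)

  ## the standard 62-channel 5-band layout has width 310
  rec62 <- eegRecording(matrix(rnorm(62 * 400), 62, 400), 200)
  expect_equal(ncol(featureValues(extractDEFeatures(rec62))), 310L)
})

test_that("short trials are skipped with a warning; empty input errors", {
  set.seed(12)
  rec <- eegRecording(matrix(rnorm(1500), 1, 1500), 200,
                      trials = rbind(c(1, 101), c(101, 1501)),
                      labels = c(1L, 0L))
  expect_warning(ft <- extractDEFeatures(rec, windowS = 1),
                 class = "msmra_warning")
  expect_equal(unique(windowLabels(ft)), 0L)

  none <- new("EEGRecording", signal = matrix(rnorm(100), 1, 100), fs = 200,
              trials = matrix(integer(0), 0, 2), labels = integer(0),
              subjectId = "s", sessionId = "k")
  expect_error(extractDEFeatures(none), class = "msmra_empty_input")
})

test_that("white-noise DE matches the filter pass-band power", {
  set.seed(13)
  fs <- 200
  rec <- eegRecording(matrix(rnorm(fs * 120), 1, fs * 120), fs)
  bands <- eegBands()
  ft <- extractDEFeatures(rec, bands = bands, windowS = 4)
  vals <- featureValues(ft)
  ## pass-band power of the forward-backward filter: mean |H|^4 over the
  ## spectrum, computed from the frequency response (independent oracle)
  for (b in seq_len(nrow(bands))) {
    bf <- signal::butter(4, c(bands$lowHz[b], bands$highHz[b]) / (fs / 2),
                         type = "pass")
    H <- signal::freqz(bf, n = 4096)
    gain <- mean(abs(H$h)^4)
    expect_lt(abs(mean(vals[, b]) - 0.5 * log(2 * pi * exp(1) * gain)), 0.1)
  }
})

test_that("scaling the signal shifts every DE entry by log(a)", {
  set.seed(14)
  rec <- eegRecording(matrix(rnorm(2 * 800), 2, 800), 200)
  f1 <- featureValues(extractDEFeatures(rec))
  rec@signal <- 3.5 * rec@signal
  f2 <- featureValues(extractDEFeatures(rec))
  expect_equal(f2 - f1, matrix(log(3.5), nrow(f1), ncol(f1)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("per-recording normalization standardizes columns and is guarded", {
  set.seed(15)
  x <- matrix(rnorm(50 * 8, mean = 3, sd = 2), 50, 8)
  x[, 4] <- 7  # constant column
  ft <- featureTensor(x, rep_len(0:1, 50))
  nf <- normalizeFeatures(ft)
  v <- featureValues(nf)
  expect_true(all(abs(colMeans(v)) < 1e-6))
  expect_true(all(abs(apply(v[, -4], 2, var) - 1) < 1e-6))
  expect_equal(v[, 4], rep(0, 50))
  expect_true(isNormalized(nf))
  expect_error(normalizeFeatures(nf), class = "msmra_already_normalized")
  expect_identical(normalizeFeatures(nf, ifNormalized = "noop"), nf)
})

test_that("polyphase resampling preserves tone frequency content", {
  rec <- toneRecording(10, fs = 500, seconds = 20)
  res <- resampleRecording(rec, 200)
  expect_equal(res@fs, 200)
  expect_equal(ncol(res@signal), 20 * 200, tolerance = 0.01)
  ## the 10 Hz tone must survive the rate change
  ft <- extractDEFeatures(res, windowS = 2)
  alpha <- featureValues(ft)[, 3]
  delta <- featureValues(ft)[, 1]
  expect_gt(mean(alpha) - mean(delta), 2)
})
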