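## Shared fixtures and independent oracles used across the test files.

## Naive O(n^2) double-loop squared-MMD with a sum of Gaussian kernels;
## deliberately scalar-at-a-time so it is independent of the vectorized path.
naiveMMD2 <- function(X, Y, sigma2, biased = TRUE) {
  k <- function(a, b) sum(vapply(sigma2, function(s)
    exp(-sum((a - b)^2) / (2 * s)), numeric(1)))
  n <- nrow(X); m <- nrow(Y)
  kxx <- 0; kyy <- 0; kxy <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) kxx <- kxx + k(X[i, ], X[j, ])
  for (i in seq_len(m)) for (j in seq_len(m)) kyy <- kyy + k(Y[i, ], Y[j, ])
  for (i in seq_len(n)) for (j in seq_len(m)) kxy <- kxy + k(X[i, ], Y[j, ])
  if (biased) {
    kxx / n^2 + kyy / m^2 - 2 * kxy / (n * m)
  } else {
    dx <- sum(vapply(seq_len(n), function(i) k(X[i, ], X[i, ]), numeric(1)))
    dy <- sum(vapply(seq_len(m), function(i) k(Y[i, ], Y[i, ]), numeric(1)))
    (kxx - dx) / (n * (n - 1)) + (kyy - dy) / (m * (m - 1)) - 2 * kxy / (n * m)
  }
}

## A tiny sinusoid-plus-noise recording for filter tests.
toneRecording <- function(freqHz, fs = 200, seconds = 60, channels = 1L,
                          amplitude = 1) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  sig <- matrix(rep(amplitude * sin(2 * pi * freqHz * t), channels),
                nrow = channels, byrow = TRUE)
  eegRecording(sig, fs)
}

## Small feature grid for partition tests: subject x session labels only.
tinyGrid <- function(nSubjects, nSessions, windows = 6L, dim = 8L,
                     nClasses = 3L, seed = 42L) {
  generateFeatureGrid(synthConfig(
    nSubjects = nSubjects, nSessions = nSessions, nClasses = nClasses,
    dim = dim, windows = windows, deltaClass = 2, deltaDomain = 0.5,
    seed = seed))
}

## A minimal partition + model pair for training-path tests.
tinyPartition <- function(seed = 7L, windows = 40L, dim = 12L) {
  grid <- generateFeatureGrid(synthConfig(
    nSubjects = 3L, nSessions = 1L, nClasses = 3L, dim = dim,
    windows = windows, deltaClass = 3, deltaDomain = 0.5, seed = seed))
  pairSources(grid[1:2], grid[[3]], "cross_subject")
}

tinyModelConfig <- function(nClasses = 3L, dim = 12L) {
  modelConfig(inDim = dim, commonDims = c(10L, 8L), branchDims = c(4L, 3L),
              branchHidden = 6L, nClasses = nClasses)
}

tinyTrainConfig <- function(seed = 1L, epochs = 5L, batchSize = 16L, ...) {
  trainConfig(seed = seed, epochs = epochs, batchSize = batchSize, ...)
}
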