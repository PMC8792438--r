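test_that("the generator produces the requested grid geometry, reproducibly", {
  cfg <- synthConfig(nSubjects = 15L, nSessions = 3L, nClasses = 3L,
                     dim = 310L, windows = 12L, seed = 3L)
  grid <- generateFeatureGrid(cfg)
  expect_length(grid, 45L)
  expect_true(all(vapply(grid, nWindows, integer(1)) == 12L))
  expect_true(all(vapply(grid, function(g) ncol(featureValues(g)),
                         integer(1)) == 310L))
  ## balanced labels
  expect_true(all(vapply(grid, function(g)
    max(abs(table(windowLabels(g)) - 4L)), double(1)) == 0))
  ## seed reproducibility
  grid2 <- generateFeatureGrid(cfg)
  expect_identical(lapply(grid, featureValues), lapply(grid2, featureValues))
  expect_error(synthConfig(nClasses = 1L), "nClasses")
})

test_that("without domain shift, a centroid rule transfers across recordings", {
  grid <- generateFeatureGrid(synthConfig(
    nSubjects = 2L, nSessions = 1L, dim = 60L, windows = 150L,
    deltaClass = 5, deltaDomain = 0, seed = 21L))
  train <- grid[[1]]; test <- grid[[2]]
  cent <- sapply(0:2, function(a)
    colMeans(featureValues(train)[windowLabels(train) == a, , drop = FALSE]))
  X <- featureValues(test)
  d2 <- outer(rowSums(X^2), rep(1, 3)) - 2 * X %*% cent +
    matrix(colSums(cent^2), nrow(X), 3, byrow = TRUE)
  acc <- mean(max.col(-d2) - 1L == windowLabels(test))
  expect_gt(acc, 0.95)
})

test_that("without class separation, cross-recording accuracy is chance", {
  grid <- generateFeatureGrid(synthConfig(
    nSubjects = 2L, nSessions = 1L, dim = 40L, windows = 300L,
    deltaClass = 0, deltaDomain = 0.5, seed = 22L))
  train <- grid[[1]]; test <- grid[[2]]
  cent <- sapply(0:2, function(a)
    colMeans(featureValues(train)[windowLabels(train) == a, , drop = FALSE]))
  X <- featureValues(test)
  d2 <- outer(rowSums(X^2), rep(1, 3)) - 2 * X %*% cent +
    matrix(colSums(cent^2), nrow(X), 3, byrow = TRUE)
  acc <- mean(max.col(-d2) - 1L == windowLabels(test))
  expect_lt(abs(acc - 1 / 3), 0.06)
})

test_that("the feature-space MMD between recordings grows with the shift", {
  mmdAt <- function(dd) {
    mean(vapply(1:25, function(s) {
      grid <- generateFeatureGrid(synthConfig(
        nSubjects = 2L, nSessions = 1L, dim = 20L, windows = 64L,
        deltaClass = 2, deltaDomain = dd, seed = 100L + s))
      mmd2(featureValues(normalizeFeatures(grid[[1]])),
           featureValues(normalizeFeatures(grid[[2]])))
    }, numeric(1)))
  }
  curve <- vapply(c(0, 1, 3), mmdAt, numeric(1))
  expect_true(all(diff(curve) > 0))
})

test_that("synthetic raw EEG has the analytic per-band DE structure", {
  powers <- rbind(c(1, 1, 1, 1, 1),
                  c(1, 1, 2, 1, 1))  # class 1 doubles Alpha power
  rec <- generateRawEEG(channels = 2L, fs = 200, trials = 8L, trialS = 25,
                        bandPowers = powers, seed = 31L)
  expect_s4_class(rec, "EEGRecording")
  ft <- extractDEFeatures(rec, windowS = 1)
  v <- featureValues(ft); y <- windowLabels(ft)
  alphaCols <- seq(3, ncol(v), by = 5)
  diffAlpha <- mean(v[y == 1L, alphaCols]) - mean(v[y == 0L, alphaCols])
  expect_equal(diffAlpha, log(2) / 2, tolerance = 0.05)
  ## other bands are unchanged
  deltaCols <- seq(1, ncol(v), by = 5)
  expect_lt(abs(mean(v[y == 1L, deltaCols]) - mean(v[y == 0L, deltaCols])),
            0.05)
  ## 62 channels x 5 bands -> width 310
  rec62 <- generateRawEEG(channels = 62L, fs = 200, trials = 1L, trialS = 2,
                          bandPowers = powers[1, , drop = FALSE], seed = 32L)
  expect_equal(ncol(featureValues(extractDEFeatures(rec62))), 310L)
})

test_that("degenerate band powers surface as degenerate DE windows", {
  rec <- generateRawEEG(channels = 1L, fs = 200, trials = 1L, trialS = 2,
                        bandPowers = c(0, 0, 0, 0, 0), seed = 33L)
  expect_true(all(rec@signal == 0))
  expect_error(extractDEFeatures(rec), class = "msmra_degenerate_window")
  expect_error(generateRawEEG(fs = 90, trials = 1L, trialS = 1,
                              bandPowers = c(1, 1, 1, 1, 1)),
               class = "msmra_invalid_config")
})

test_that("the default suite is ten cross-subject partitions of two domains", {
  suite <- defaultSynthSuite(seed = 4L)
  expect_length(suite, 10L)
  expect_true(all(vapply(suite, nDomains, integer(1)) == 2L))
  expect_true(all(vapply(suite, function(p) p@scenario, character(1)) ==
                    "cross_subject"))
})
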