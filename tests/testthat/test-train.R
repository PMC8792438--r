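test_that("the trade-off schedule matches its closed form and is monotone", {
  expect_identical(alphaSchedule(0, 50), 0)
  expect_equal(alphaSchedule(25, 50), 0.986614, tolerance = 1e-6)
  expect_equal(alphaSchedule(50, 50), 0.999909, tolerance = 1e-6)
  grid <- seq(0, 1000)
  a <- alphaSchedule(grid, 1000)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a < 1))
  expect_error(alphaSchedule(1, 0), class = "msmra_invalid_config")
})

test_that("cross-entropy matches hand-computed values", {
  perfect <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(classificationLoss(perfect, 0L), 0, tolerance = 1e-10)
  unif <- matrix(1 / 3, 4, 3)
  expect_equal(classificationLoss(unif, c(0L, 1L, 2L, 0L)), log(3),
               tolerance = 1e-12)
  p <- matrix(c(0.5, 0.25, 0.25), 1, 3)
  expect_equal(classificationLoss(p, 0L), log(2), tolerance = 1e-12)
  expect_error(classificationLoss(unif, c(0L, 1L)), class = "msmra_shape")
  expect_warning(classificationLoss(matrix(c(0, 1), 1, 2), 0L),
                 class = "msmra_warning")
})

test_that("the joint objective decomposes by distributivity", {
  set.seed(501)
  for (rep in 1:25) {
    N <- sample(1:4, 1)
    perRep <- lapply(seq_len(N), function(i) abs(rnorm(3)))
    est <- new("MMDEstimate", perRepresentation = perRep,
               perDomain = vapply(perRep, sum, numeric(1)),
               total = sum(unlist(perRep)))
    cls <- abs(rnorm(N))
    alpha <- runif(1)
    expect_equal(totalLoss(cls, est, alpha),
                 sum(cls) + alpha * est@total, tolerance = 1e-12)
  }
  est1 <- new("MMDEstimate", perRepresentation = list(0.5),
              perDomain = 0.5, total = 0.5)
  expect_equal(totalLoss(1.0, est1, 1), 1.5)
  expect_equal(totalLoss(c(1, 2), new("MMDEstimate",
    perRepresentation = list(1, 2), perDomain = c(1, 2), total = 3), 0), 3)
  expect_error(totalLoss(c(1, 2, 3), est1, 1), class = "msmra_domain_count")
})

test_that("training reduces the joint loss and flags the model trained", {
  part <- tinyPartition()
  fit <- trainMSMRA(part, tinyTrainConfig(epochs = 15L),
                    modelConfig = tinyModelConfig())
  expect_true(fit$model@trained)
  expect_equal(nrow(fit$history), 15L)
  ## classification improves; the joint loss is confounded by the alpha ramp
  expect_lt(fit$history$clsLoss[15], fit$history$clsLoss[1])
  expect_equal(fit$history$alpha[1], 0)
  ## evaluation returns a coherent confusion matrix
  ev <- evaluateModel(fit$model, part@target)
  expect_gte(ev$accuracy, 0)
  expect_equal(sum(diag(ev$confusion)) / sum(ev$confusion), ev$accuracy)
  expect_equal(rowSums(ev$confusion),
               as.vector(table(factor(windowLabels(part@target),
                                      levels = 0:2))), ignore_attr = TRUE)
})

test_that("training is deterministic given the seed", {
  part <- tinyPartition()
  cfg <- tinyTrainConfig(epochs = 4L)
  f1 <- trainMSMRA(part, cfg, modelConfig = tinyModelConfig())
  f2 <- trainMSMRA(part, cfg, modelConfig = tinyModelConfig())
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@params, f2$model@params)
})

test_that("disabling adaptation pins alpha at zero", {
  part <- tinyPartition()
  fit <- trainMSMRA(part, tinyTrainConfig(epochs = 3L, adapt = FALSE),
                    modelConfig = tinyModelConfig())
  expect_true(all(fit$history$alpha == 0))
  expect_equal(fit$history$totalLoss, fit$history$clsLoss)
})

test_that("the single-branch ablation runs end-to-end with width 96", {
  part <- tinyPartition()
  fit <- trainMSMRA(part, tinyTrainConfig(epochs = 2L, mdsfe = FALSE))
  expect_equal(fit$model@config@branchDims, 96L)
  ev <- evaluateModel(fit$model, part@target)
  expect_true(is.finite(ev$accuracy))
})

test_that("scenario runs aggregate with a population SD", {
  grid <- generateFeatureGrid(synthConfig(
    nSubjects = 3L, nSessions = 1L, nClasses = 3L, dim = 10L, windows = 30L,
    deltaClass = 3, deltaDomain = 0.5, seed = 9L))
  splits <- leaveOneOutSplits(grid, "cross_subject", allowSingleton = TRUE)
  res <- runScenario(splits, tinyTrainConfig(epochs = 3L),
                     modelConfig = tinyModelConfig(dim = 10L))
  expect_equal(nrow(res$results), 3L)
  expect_named(res$results,
               c("split_id", "scenario", "n_domains", "accuracy", "seed"))
  expect_equal(res$mean, mean(res$results$accuracy))
  expect_equal(res$sd, sqrt(mean((res$results$accuracy - res$mean)^2)))
  ## per-split seeds advance deterministically
  expect_equal(res$results$seed, 1:3)
})

test_that("unlabeled sources are rejected", {
  part <- tinyPartition()
  part@sources[[1]]@members[[1]]@labels <-
    rep(NA_integer_, nWindows(part@sources[[1]]@members[[1]]))
  expect_error(
    suppressWarnings(trainMSMRA(part,
                                tinyTrainConfig(epochs = 1L,
                                                normalize = FALSE),
                                modelConfig = tinyModelConfig())),
    class = "msmra_missing_labels")
})
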