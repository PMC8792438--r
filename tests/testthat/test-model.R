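test_that("the forward pass honors the 310 -> 64 -> (48,32,16) -> 96 -> M chain", {
  for (M in c(3L, 4L)) {
    m <- newMSMRAModel(modelConfig(nClasses = M), nDomains = 2L, seed = 5L)
    X <- matrix(rnorm(7 * 310), 7, 310)
    F <- commonExtract(m, X)
    expect_equal(dim(F), c(7L, 64L))
    reps <- mdsfeExtract(m, F, 1L)
    expect_equal(vapply(reps, ncol, integer(1)), c(48L, 32L, 16L))
    concat <- do.call(cbind, reps)
    expect_equal(ncol(concat), 96L)
    probs <- classifyDomain(m, concat, 1L)
    expect_equal(dim(probs), c(7L, M))
    expect_equal(rowSums(probs), rep(1, 7), tolerance = 1e-6)
    expect_true(all(probs > 0 & probs < 1))
  }
})

test_that("shape and index violations are rejected", {
  m <- newMSMRAModel(tinyModelConfig(), 2L, seed = 1L)
  expect_error(commonExtract(m, matrix(0, 2, 5)), class = "msmra_shape")
  expect_error(mdsfeExtract(m, matrix(0, 2, 8), 3L), class = "msmra_index")
  expect_error(classifyDomain(m, matrix(0, 2, 5), 1L), class = "msmra_shape")
})

test_that("extractors are deterministic and row-permutation consistent", {
  m <- newMSMRAModel(tinyModelConfig(), 2L, seed = 2L)
  X <- matrix(rnorm(6 * 12), 6, 12)
  F1 <- commonExtract(m, X)
  expect_identical(F1, commonExtract(m, X))
  ## identical rows map to identical rows
  X2 <- rbind(X[1, ], X[1, ])
  F2 <- commonExtract(m, X2)
  expect_identical(F2[1, ], F2[2, ])
  ## permuting input rows permutes outputs identically
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(commonExtract(m, X[perm, ]), F1[perm, ])

  ## zero parameters map everything to zero
  mz <- m
  mz@params <- msmra:::zeroLike(mz@params)
  expect_equal(commonExtract(mz, X), matrix(0, 6, 8), ignore_attr = TRUE)
})

test_that("distinct domains have independent parameters", {
  m <- newMSMRAModel(tinyModelConfig(), 3L, seed = 3L)
  F <- matrix(rnorm(5 * 8), 5, 8)
  r1 <- mdsfeExtract(m, F, 1L)
  r2 <- mdsfeExtract(m, F, 2L)
  expect_false(isTRUE(all.equal(r1[[1]], r2[[1]])))
})

test_that("analytic gradients match finite differences on the joint objective", {
  set.seed(401)
  m <- newMSMRAModel(tinyModelConfig(), 2L, seed = 4L)
  srcX <- list(matrix(rnorm(60), 5, 12), matrix(rnorm(60), 5, 12))
  srcY <- list(sample(0:2, 5, TRUE), sample(0:2, 5, TRUE))
  tgt <- matrix(rnorm(48), 4, 12)
  kc <- kernelConfig(bandwidths = c(1, 4))
  st <- msmra:::msmraStep(m, srcX, srcY, tgt, alpha = 0.7, kernel = kc)
  lossAt <- function(mutate) {
    mm <- m
    mm@params <- mutate(mm@params)
    msmra:::msmraStep(mm, srcX, srcY, tgt, 0.7, kc, withGrads = FALSE)$total
  }
  eps <- 1e-6
  checks <- list(
    list(get = function(p) p$common[[1]]$W[1, 2],
         set = function(p, v) { p$common[[1]]$W[1, 2] <- v; p },
         grad = st$grads$common[[1]]$W[1, 2]),
    list(get = function(p) p$domains[[1]]$branches[[2]][[1]]$W[2, 1],
         set = function(p, v) { p$domains[[1]]$branches[[2]][[1]]$W[2, 1] <- v; p },
         grad = st$grads$domains[[1]]$branches[[2]][[1]]$W[2, 1]),
    list(get = function(p) p$domains[[2]]$cls$b[1],
         set = function(p, v) { p$domains[[2]]$cls$b[1] <- v; p },
         grad = st$grads$domains[[2]]$cls$b[1]),
    list(get = function(p) p$common[[2]]$b[3],
         set = function(p, v) { p$common[[2]]$b[3] <- v; p },
         grad = st$grads$common[[2]]$b[3]))
  for (ck in checks) {
    v0 <- ck$get(m@params)
    num <- (lossAt(function(p) ck$set(p, v0 + eps)) -
              lossAt(function(p) ck$set(p, v0 - eps))) / (2 * eps)
    expect_equal(ck$grad, num, tolerance = 1e-4)
  }
})

test_that("one domain's loss is isolated from other domains' parameters", {
  set.seed(402)
  m <- newMSMRAModel(tinyModelConfig(), 2L, seed = 6L)
  srcX <- list(matrix(rnorm(60), 5, 12), matrix(rnorm(60), 5, 12))
  srcY <- list(sample(0:2, 5, TRUE), sample(0:2, 5, TRUE))
  tgt <- matrix(rnorm(48), 4, 12)
  kc <- kernelConfig(bandwidths = 2)
  base <- msmra:::msmraStep(m, srcX, srcY, tgt, alpha = 0.5, kernel = kc,
                            withGrads = FALSE)
  ## perturbing domain 2's branch and head leaves domain 1's losses untouched
  m2 <- m
  m2@params$domains[[2]]$branches[[1]][[1]]$W[] <-
    m2@params$domains[[2]]$branches[[1]][[1]]$W + 0.3
  m2@params$domains[[2]]$cls$W[] <- m2@params$domains[[2]]$cls$W - 0.2
  pert <- msmra:::msmraStep(m2, srcX, srcY, tgt, alpha = 0.5, kernel = kc,
                            withGrads = FALSE)
  expect_identical(pert$clsLoss[1], base$clsLoss[1])
  expect_identical(pert$mmd@perDomain[1], base$mmd@perDomain[1])
  expect_false(isTRUE(all.equal(pert$clsLoss[2], base$clsLoss[2])))
})

test_that("target prediction fuses the domain heads by uniform averaging", {
  m <- newMSMRAModel(tinyModelConfig(), 2L, seed = 7L)
  X <- matrix(rnorm(4 * 12), 4, 12)
  expect_error(predictTarget(m, X), class = "msmra_not_trained")
  m@trained <- TRUE
  pr <- predictTarget(m, X)
  F <- commonExtract(m, X)
  manual <- (classifyDomain(m, do.call(cbind, mdsfeExtract(m, F, 1L)), 1L) +
               classifyDomain(m, do.call(cbind, mdsfeExtract(m, F, 2L)), 2L)) / 2
  expect_equal(pr$probs, manual)
  expect_equal(pr$labels, max.col(manual, ties.method = "first") - 1L)

  ## hand-averaged two-head example: (0.6,0.4) and (0.2,0.8) -> class 2
  avg <- (c(0.6, 0.4) + c(0.2, 0.8)) / 2
  expect_equal(avg, c(0.4, 0.6))
  expect_equal(which.max(avg) - 1L, 1L)

  ## N = 1 reduces to the single head
  m1 <- newMSMRAModel(tinyModelConfig(), 1L, seed = 8L)
  m1@trained <- TRUE
  pr1 <- predictTarget(m1, X)
  F1 <- commonExtract(m1, X)
  h1 <- classifyDomain(m1, do.call(cbind, mdsfeExtract(m1, F1, 1L)), 1L)
  expect_equal(pr1$labels, max.col(h1, ties.method = "first") - 1L)
})
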