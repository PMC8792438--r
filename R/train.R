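#' Dynamic trade-off schedule for the adaptation weight
#'
#' \deqn{\alpha(i) = \frac{2}{1 + e^{-10 i / \mathrm{epochs}}} - 1}
#' evaluated at the 0-based epoch index, so \eqn{\alpha(0) = 0} and training
#' prioritizes classification before the MMD alignment ramps in; the value is
#' strictly increasing and bounded in \eqn{[0, 1)}.
#'
#' @param i epoch index, \code{0 <= i <= epochs}.
#' @param epochs total number of epochs (> 0).
#' @return The trade-off coefficient.
#' @export
alphaSchedule <- function(i, epochs) {
  if (length(epochs) != 1L || epochs <= 0)
    msmraStop("msmra_invalid_config", "epochs must be positive")
  if (any(i < 0) || any(i > epochs))
    msmraStop("msmra_invalid_config", "epoch index outside 0..epochs")
  2 / (1 + exp(-10 * i / epochs)) - 1
}

#' Cross-entropy classification loss
#'
#' Mean over the batch of \code{-log p[true class]} with the probability of
#' the true class floored at 1e-12.
#'
#' @param probabilities b x M matrix of valid class distributions.
#' @param labels integer vector of 0-based labels in \code{0..M-1}.
#' @return Mean cross-entropy (nats).
#' @export
classificationLoss <- function(probabilities, labels) {
  if (nrow(probabilities) != length(labels))
    msmraStop("msmra_shape", "need one label per probability row")
  if (any(labels < 0L) || any(labels >= ncol(probabilities)))
    msmraStop("msmra_shape", "labels outside 0..M-1")
  p <- probabilities[cbind(seq_along(labels), labels + 1L)]
  if (any(p < 1e-12))
    msmraWarn("%d true-class probabilities below 1e-12 were clamped",
              sum(p < 1e-12))
  -mean(log(pmax(p, 1e-12)))
}

#' Joint objective: classification plus weighted adaptation loss
#'
#' \deqn{L = \sum_{i=1}^{N} \left( L^i_{cls} + \alpha\, \mathrm{MMD}^i \right)}
#' which by distributivity equals \eqn{\sum_i L^i_{cls} + \alpha\,\mathrm{MMD}_{total}}.
#'
#' @param perDomainCls numeric vector of N classification losses.
#' @param mmdEstimate an [MMDEstimate-class] over the same N domains.
#' @param alpha non-negative trade-off weight.
#' @return The total loss (scalar).
#' @export
totalLoss <- function(perDomainCls, mmdEstimate, alpha) {
  stopifnot(is(mmdEstimate, "MMDEstimate"), alpha >= 0)
  if (length(perDomainCls) != length(mmdEstimate@perDomain))
    msmraStop("msmra_domain_count",
              "%d classification losses but %d MMD domains",
              length(perDomainCls), length(mmdEstimate@perDomain))
  sum(perDomainCls + alpha * mmdEstimate@perDomain)
}

## Adam update; state mirrors the nested parameter list.
adamInit <- function(params) list(m = zeroLike(params), v = zeroLike(params), t = 0L)

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapNested(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- mapNested(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- mapNested(state$m, state$v, function(m, v)
    lr * (m / c1) / (sqrt(v / c2) + eps))
  list(params = mapNested(params, upd, `-`), state = state)
}

## Draw a batch of row indices; with replacement when the pool is smaller.
drawBatch <- function(n, batchSize) {
  sample.int(n, batchSize, replace = batchSize > n)
}

#' Train a model on one domain partition
#'
#' Per optimization step, one minibatch is drawn from each source domain's
#' pooled windows and one from the (unlabeled) target; all domains are
#' forwarded; each domain contributes its cross-entropy loss on source labels
#' plus \code{alpha} times the summed MMD between its r source and target
#' branch representations; a single Adam step minimizes the joint objective.
#' The schedule [alphaSchedule()] advances per epoch (or per step if
#' configured). Fully deterministic given \code{config@seed}.
#'
#' If \code{config@normalize} is TRUE, every recording is standardized
#' per-recording before pooling (a no-op for already-normalized tensors).
#' If \code{config@mdsfe} is FALSE, the multi-representation branches are
#' replaced by a single branch of width \code{sum(branchDims)} per domain so
#' the classifier geometry is unchanged.
#'
#' @param partition a [DomainPartition-class].
#' @param config a [TrainConfig-class].
#' @param model optional pre-built [MSMRAModel-class]; built from
#'   \code{modelConfig} when NULL.
#' @param modelConfig architecture used when \code{model} is NULL; its
#'   \code{nClasses} must cover the source labels.
#' @param verbose print a line per epoch.
#' @return List with \code{model} (trained) and \code{history} (data.frame
#'   with one row per epoch: epoch, alpha, per-epoch mean classification
#'   loss, MMD total and joint loss).
#' @export
trainMSMRA <- function(partition, config = trainConfig(), model = NULL,
                       modelConfig = NULL, verbose = FALSE) {
  stopifnot(is(partition, "DomainPartition"), is(config, "TrainConfig"))
  set.seed(config@seed)
  N <- nDomains(partition)

  prep <- function(m) {
    if (config@normalize) normalizeFeatures(m, ifNormalized = "noop") else m
  }
  srcX <- vector("list", N)
  srcY <- vector("list", N)
  for (i in seq_len(N)) {
    dom <- partition@sources[[i]]
    members <- lapply(dom@members, prep)
    srcX[[i]] <- do.call(rbind, lapply(members, featureValues))
    srcY[[i]] <- unlist(lapply(members, windowLabels), use.names = FALSE)
    if (length(srcY[[i]]) == 0L || anyNA(srcY[[i]]))
      msmraStop("msmra_missing_labels", "source domain %d has no labels", i)
  }
  tgtX <- featureValues(prep(partition@target))

  if (is.null(model)) {
    if (is.null(modelConfig)) {
      M <- max(unlist(srcY)) + 1L
      modelConfig <- msmra::modelConfig(inDim = ncol(tgtX), nClasses = max(M, 2L))
    }
    if (!config@mdsfe)
      modelConfig <- new("ModelConfig", inDim = modelConfig@inDim,
                         commonDims = modelConfig@commonDims,
                         branchDims = sum(modelConfig@branchDims),
                         branchHidden = modelConfig@branchHidden,
                         nClasses = modelConfig@nClasses,
                         slope = modelConfig@slope)
    model <- newMSMRAModel(modelConfig, N, seed = config@seed)
    set.seed(config@seed + 1L)  # decouple batch draws from init draws
  }
  if (any(vapply(srcX, nrow, integer(1)) < config@batchSize) ||
      nrow(tgtX) < config@batchSize)
    msmraWarn("batch size %d exceeds a domain's window count; sampling with replacement",
              config@batchSize)

  ## enough steps per epoch to cover the largest domain once
  stepsPerEpoch <- max(1L, as.integer(ceiling(
    max(vapply(srcX, nrow, integer(1))) / config@batchSize)))
  opt <- adamInit(model@params)
  hist <- data.frame(epoch = integer(0), alpha = numeric(0),
                     clsLoss = numeric(0), mmd = numeric(0),
                     totalLoss = numeric(0))
  totalSteps <- config@epochs * stepsPerEpoch
  stepIdx <- 0L
  for (ep in seq_len(config@epochs) - 1L) {
    accCls <- 0; accMmd <- 0; accTot <- 0
    alpha <- if (config@adapt) alphaSchedule(ep, config@epochs) else 0
    for (st in seq_len(stepsPerEpoch)) {
      if (config@adapt && config@alphaPerStep)
        alpha <- alphaSchedule(stepIdx, totalSteps)
      bS <- lapply(seq_len(N), function(i)
        drawBatch(nrow(srcX[[i]]), config@batchSize))
      bT <- drawBatch(nrow(tgtX), config@batchSize)
      res <- msmraStep(model,
                       lapply(seq_len(N), function(i)
                         srcX[[i]][bS[[i]], , drop = FALSE]),
                       lapply(seq_len(N), function(i) srcY[[i]][bS[[i]]]),
                       tgtX[bT, , drop = FALSE],
                       alpha, config@kernel, withGrads = TRUE,
                       computeMmd = config@adapt)
      au <- adamStep(model@params, res$grads, opt, config@lr)
      model@params <- au$params
      opt <- au$state
      accCls <- accCls + sum(res$clsLoss)
      accMmd <- accMmd + res$mmd@total
      accTot <- accTot + res$total
      stepIdx <- stepIdx + 1L
    }
    hist <- rbind(hist, data.frame(
      epoch = ep, alpha = alpha, clsLoss = accCls / stepsPerEpoch,
      mmd = accMmd / stepsPerEpoch, totalLoss = accTot / stepsPerEpoch))
    if (verbose)
      message(sprintf("epoch %2d  alpha %.4f  cls %.4f  mmd %.4f  total %.4f",
                      ep, alpha, accCls / stepsPerEpoch, accMmd / stepsPerEpoch,
                      accTot / stepsPerEpoch))
  }
  model@trained <- TRUE
  list(model = model, history = hist)
}

#' Score a trained model on a labeled target recording
#'
#' @param model a trained [MSMRAModel-class].
#' @param target a [FeatureTensor-class] whose labels are used for scoring
#'   only.
#' @param normalize standardize the target per-recording before scoring
#'   (must match how the model was trained).
#' @return List with \code{accuracy} and an M x M \code{confusion} matrix
#'   (rows = true class, columns = predicted; row sums are class counts).
#' @export
evaluateModel <- function(model, target, normalize = TRUE) {
  stopifnot(is(target, "FeatureTensor"))
  if (normalize) target <- normalizeFeatures(target, ifNormalized = "noop")
  X <- featureValues(target)
  y <- windowLabels(target)
  if (nrow(X) != length(y))
    msmraStop("msmra_shape", "label/window count mismatch")
  pred <- predictTarget(model, X)$labels
  M <- model@config@nClasses
  conf <- matrix(0L, M, M, dimnames = list(true = 0:(M - 1), pred = 0:(M - 1)))
  for (k in seq_along(y)) conf[y[k] + 1L, pred[k] + 1L] <- conf[y[k] + 1L, pred[k] + 1L] + 1L
  list(accuracy = mean(pred == y), confusion = conf)
}

#' Train and evaluate over a list of partitions
#'
#' Trains one model per partition (seeding run k with
#' \code{config@seed + k - 1}) and reports per-split target accuracy plus
#' the mean and population standard deviation.
#'
#' @param splits list of [DomainPartition-class] objects.
#' @param config a [TrainConfig-class].
#' @param modelConfig optional [ModelConfig-class] shared by all splits.
#' @param verbose print one line per split.
#' @return List with \code{results} (data.frame: split_id, scenario,
#'   n_domains, accuracy, seed), \code{mean} and \code{sd}.
#' @export
runScenario <- function(splits, config = trainConfig(), modelConfig = NULL,
                        verbose = FALSE) {
  if (length(splits) == 0L)
    msmraStop("msmra_empty_input", "no partitions supplied")
  rows <- vector("list", length(splits))
  for (k in seq_along(splits)) {
    cfg <- config
    cfg@seed <- config@seed + k - 1L
    acc <- tryCatch({
      fit <- trainMSMRA(splits[[k]], cfg, modelConfig = modelConfig)
      evaluateModel(fit$model, splits[[k]]@target,
                    normalize = cfg@normalize)$accuracy
    }, msmra_error = function(e) {
      msmraWarn("split %d failed (%s); excluded from aggregates", k,
                conditionMessage(e))
      NA_real_
    })
    rows[[k]] <- data.frame(split_id = k, scenario = splits[[k]]@scenario,
                            n_domains = nDomains(splits[[k]]),
                            accuracy = acc, seed = cfg@seed)
    if (verbose)
      message(sprintf("split %2d/%d: accuracy %.4f", k, length(splits), acc))
  }
  results <- do.call(rbind, rows)
  ok <- results$accuracy[!is.na(results$accuracy)]
  list(results = results, mean = mean(ok), sd = popSD(ok))
}

#' Ablation table over the normalization and multi-representation switches
#'
#' Re-runs [runScenario()] with the four switch combinations (full model,
#' without per-recording normalization, without the multi-representation
#' branches, without both) and tabulates mean accuracy and population SD.
#'
#' @param splits list of [DomainPartition-class] objects.
#' @param config base [TrainConfig-class] (its switches define "full").
#' @param modelConfig optional shared [ModelConfig-class].
#' @param verbose passed through.
#' @return data.frame with columns variant, normalize, mdsfe, mean_accuracy,
#'   sd_accuracy.
#' @export
runAblation <- function(splits, config = trainConfig(), modelConfig = NULL,
                        verbose = FALSE) {
  variants <- data.frame(
    variant = c("full", "wo_normalization", "wo_mdsfe",
                "wo_normalization_mdsfe"),
    normalize = c(TRUE, FALSE, TRUE, FALSE),
    mdsfe = c(TRUE, TRUE, FALSE, FALSE))
  out <- variants
  out$mean_accuracy <- NA_real_
  out$sd_accuracy <- NA_real_
  for (v in seq_len(nrow(variants))) {
    cfg <- config
    cfg@normalize <- variants$normalize[v]
    cfg@mdsfe <- variants$mdsfe[v]
    res <- runScenario(splits, cfg, modelConfig = modelConfig,
                       verbose = verbose)
    out$mean_accuracy[v] <- res$mean
    out$sd_accuracy[v] <- res$sd
  }
  out
}
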