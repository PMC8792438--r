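## One affine layer: list(W = in x out, b = out).
initLayer <- function(nin, nout) {
  lim <- sqrt(1 / nin)
  list(W = matrix(runif(nin * nout, -lim, lim), nin, nout),
       b = runif(nout, -lim, lim))
}

initStack <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(k)
    initLayer(dims[k], dims[k + 1L]))
}

#' Build an untrained model
#'
#' Allocates the shared extractor, the N x r per-domain branch stacks and the
#' N classifier heads with seeded uniform fan-in initialization
#' (\code{U(-1/sqrt(fan_in), 1/sqrt(fan_in))}).
#'
#' @param config a [ModelConfig-class].
#' @param nDomains number of source domains N.
#' @param seed initialization seed (recorded on the model).
#' @return An untrained [MSMRAModel-class].
#' @export
newMSMRAModel <- function(config = modelConfig(), nDomains, seed = 1L) {
  stopifnot(is(config, "ModelConfig"), nDomains >= 1L)
  set.seed(seed)
  commonDims <- c(config@inDim, config@commonDims)
  low <- config@commonDims[length(config@commonDims)]
  branchDims <- lapply(config@branchDims, function(w)
    c(low, config@branchHidden, w))
  concatW <- sum(config@branchDims)
  params <- list(
    common = initStack(commonDims),
    domains = lapply(seq_len(nDomains), function(i)
      list(branches = lapply(branchDims, initStack),
           cls = initLayer(concatW, config@nClasses))))
  new("MSMRAModel", config = config, nDomains = as.integer(nDomains),
      params = params, trained = FALSE, seed = as.integer(seed))
}

## Forward through an affine + leaky-rectifier stack, keeping caches
## (inputs and pre-activations) for backprop. `activateLast` keeps the final
## layer nonlinear for extractor stacks, linear for classifier heads.
forwardStack <- function(stack, X, slope, activateLast = TRUE) {
  caches <- vector("list", length(stack))
  H <- X
  for (k in seq_along(stack)) {
    pre <- sweep(H %*% stack[[k]]$W, 2L, stack[[k]]$b, "+")
    act <- if (k < length(stack) || activateLast) leakyRelu(pre, slope) else pre
    caches[[k]] <- list(input = H, pre = pre)
    H <- act
  }
  list(out = H, caches = caches)
}

## Backprop through a stack given dL/d(output); returns layer gradients and
## dL/d(input).
backwardStack <- function(stack, caches, dOut, slope, activateLast = TRUE) {
  grads <- vector("list", length(stack))
  d <- dOut
  for (k in rev(seq_along(stack))) {
    if (k < length(stack) || activateLast)
      d <- d * leakyReluGrad(caches[[k]]$pre, slope)
    grads[[k]] <- list(W = crossprod(caches[[k]]$input, d), b = colSums(d))
    d <- tcrossprod(d, stack[[k]]$W)
  }
  list(grads = grads, dInput = d)
}

#' Shared low-level feature extraction
#'
#' Maps a windows x inDim batch through the shared three-layer extractor to
#' the 64-dimensional low-level feature space (every layer affine + leaky
#' rectifier). Deterministic given the parameters.
#'
#' @param model an [MSMRAModel-class].
#' @param batch windows x inDim numeric matrix.
#' @return windows x 64 matrix (width = last common layer).
#' @export
commonExtract <- function(model, batch) {
  checkWidth(batch, model@config@inDim, "common extractor input")
  forwardStack(model@params$common, batch, model@config@slope)$out
}

#' Per-domain multi-representation extraction
#'
#' Runs domain \code{i}'s r parallel branch stacks on a low-level feature
#' batch, producing the multi-representation list (widths 48, 32, 16 in the
#' standard configuration).
#'
#' @param model an [MSMRAModel-class].
#' @param features windows x 64 low-level feature batch.
#' @param i domain index in \code{1..N}.
#' @return List of r matrices.
#' @export
mdsfeExtract <- function(model, features, i) {
  checkDomainIndex(model, i)
  low <- model@config@commonDims[length(model@config@commonDims)]
  checkWidth(features, low, "branch input")
  lapply(model@params$domains[[i]]$branches, function(st)
    forwardStack(st, features, model@config@slope)$out)
}

#' Per-domain softmax classification
#'
#' @param model an [MSMRAModel-class].
#' @param concat windows x 96 concatenated representation batch.
#' @param i domain index.
#' @return windows x M matrix of class probabilities (rows sum to 1).
#' @export
classifyDomain <- function(model, concat, i) {
  checkDomainIndex(model, i)
  checkWidth(concat, sum(model@config@branchDims), "classifier input")
  cls <- model@params$domains[[i]]$cls
  softmaxRows(sweep(concat %*% cls$W, 2L, cls$b, "+"))
}

checkWidth <- function(batch, expected, what) {
  if (!is.matrix(batch) || ncol(batch) != expected)
    msmraStop("msmra_shape", "%s must have width %d (got %s)", what, expected,
              if (is.matrix(batch)) ncol(batch) else "a non-matrix")
  invisible(TRUE)
}

checkDomainIndex <- function(model, i) {
  if (!isWholeNumber(i) || i < 1 || i > model@nDomains)
    msmraStop("msmra_index", "domain index %s outside 1..%d",
              format(i), model@nDomains)
  invisible(TRUE)
}

## Full forward pass of domain i on a batch (after the common extractor).
domainForward <- function(model, features, i) {
  reps <- mdsfeExtract(model, features, i)
  concat <- do.call(cbind, reps)
  list(reps = reps, concat = concat,
       probs = classifyDomain(model, concat, i))
}

#' Predict target labels by fusing the N domain heads
#'
#' Runs the shared extractor, then every domain's branches and classifier,
#' and averages the N softmax outputs uniformly. The predicted label is the
#' argmax of the averaged distribution, ties broken toward the lowest class
#' index. Labels are returned as 0-based class codes, matching
#' [FeatureTensor-class] labels.
#'
#' @param model a trained [MSMRAModel-class].
#' @param batch windows x inDim target batch.
#' @return List with \code{labels} (integer, 0-based) and \code{probs}
#'   (windows x M averaged distribution).
#' @export
predictTarget <- function(model, batch) {
  if (!model@trained)
    msmraStop("msmra_not_trained", "model has not been trained")
  F <- commonExtract(model, batch)
  probs <- 0
  for (i in seq_len(model@nDomains))
    probs <- probs + domainForward(model, F, i)$probs
  probs <- probs / model@nDomains
  list(labels = max.col(probs, ties.method = "first") - 1L, probs = probs)
}

## ---- joint forward/backward used by the training loop -------------------

## Computes, for one optimization step, the per-domain classification losses,
## the MMD estimate across domains and representations, the total objective,
## and (optionally) gradients for every parameter. srcX/srcY are lists over
## domains; the single target batch is forwarded through the shared extractor
## once and through every domain's branches.
msmraStep <- function(model, srcX, srcY, tgtX, alpha,
                      kernel = kernelConfig(), withGrads = TRUE,
                      computeMmd = TRUE) {
  cfg <- model@config
  slope <- cfg@slope
  N <- model@nDomains
  common <- model@params$common

  fT <- forwardStack(common, tgtX, slope)
  fS <- lapply(srcX, function(X) forwardStack(common, X, slope))

  clsLoss <- numeric(N)
  perRep <- vector("list", N)
  grads <- if (withGrads) zeroLike(model@params) else NULL
  dCommonTarget <- 0

  for (i in seq_len(N)) {
    dom <- model@params$domains[[i]]
    r <- length(dom$branches)
    bS <- lapply(dom$branches, function(st) forwardStack(st, fS[[i]]$out, slope))
    bT <- lapply(dom$branches, function(st) forwardStack(st, fT$out, slope))

    concat <- do.call(cbind, lapply(bS, `[[`, "out"))
    logits <- sweep(concat %*% dom$cls$W, 2L, dom$cls$b, "+")
    probs <- softmaxRows(logits)
    b <- nrow(probs)
    yIdx <- cbind(seq_len(b), srcY[[i]] + 1L)
    clsLoss[i] <- -mean(log(pmax(probs[yIdx], 1e-12)))

    needMmdGrads <- withGrads && alpha > 0
    mm <- lapply(seq_len(r), function(j) {
      if (needMmdGrads) mmd2WithGrad(bS[[j]]$out, bT[[j]]$out, kernel)
      else if (computeMmd || alpha > 0)
        list(value = mmd2(bS[[j]]$out, bT[[j]]$out, kernel))
      else list(value = 0)
    })
    perRep[[i]] <- vapply(mm, `[[`, numeric(1), "value")

    if (withGrads) {
      oneHot <- matrix(0, b, cfg@nClasses)
      oneHot[yIdx] <- 1
      dLogits <- (probs - oneHot) / b
      grads$domains[[i]]$cls$W <- crossprod(concat, dLogits)
      grads$domains[[i]]$cls$b <- colSums(dLogits)
      dConcat <- tcrossprod(dLogits, dom$cls$W)

      widths <- vapply(bS, function(x) ncol(x$out), integer(1))
      ends <- cumsum(widths)
      starts <- ends - widths + 1L
      dFs <- 0
      dFt <- 0
      for (j in seq_len(r)) {
        dRepS <- dConcat[, starts[j]:ends[j], drop = FALSE]
        if (needMmdGrads) dRepS <- dRepS + alpha * mm[[j]]$gX
        bwS <- backwardStack(dom$branches[[j]], bS[[j]]$caches, dRepS, slope)
        grads$domains[[i]]$branches[[j]] <-
          addLayerGrads(grads$domains[[i]]$branches[[j]], bwS$grads)
        dFs <- dFs + bwS$dInput
        if (needMmdGrads) {
          bwT <- backwardStack(dom$branches[[j]], bT[[j]]$caches,
                               alpha * mm[[j]]$gY, slope)
          grads$domains[[i]]$branches[[j]] <-
            addLayerGrads(grads$domains[[i]]$branches[[j]], bwT$grads)
          dFt <- dFt + bwT$dInput
        }
      }
      bwC <- backwardStack(common, fS[[i]]$caches, dFs, slope)
      grads$common <- addLayerGrads(grads$common, bwC$grads)
      dCommonTarget <- dCommonTarget + dFt
    }
  }
  if (withGrads && !identical(dCommonTarget, 0)) {
    bwCT <- backwardStack(common, fT$caches, dCommonTarget, slope)
    grads$common <- addLayerGrads(grads$common, bwCT$grads)
  }
  perDomain <- vapply(perRep, sum, numeric(1))
  mmdEst <- new("MMDEstimate", perRepresentation = perRep,
                perDomain = perDomain, total = sum(perDomain))
  list(clsLoss = clsLoss, mmd = mmdEst,
       total = sum(clsLoss + alpha * perDomain), grads = grads)
}

## ---- nested parameter-list arithmetic ------------------------------------

zeroLike <- function(p) {
  if (is.list(p)) lapply(p, zeroLike) else p * 0
}

addLayerGrads <- function(a, b) {
  if (is.null(a)) return(b)
  mapNested(a, b, `+`)
}

mapNested <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- mapNested(a[[k]], b[[k]], f)
    out
  } else {
    f(a, b)
  }
}

flattenParams <- function(p) {
  if (is.list(p)) unlist(lapply(p, flattenParams), use.names = FALSE)
  else as.numeric(p)
}
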