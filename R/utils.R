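#' @import methods
#' @importFrom stats rnorm runif var sd median
#' @importFrom Rcpp evalCpp
#' @useDynLib msmra, .registration = TRUE
NULL

## Classed conditions so callers (and the CLI) can map failures to exit codes.
msmraStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "msmra_error", "error", "condition")))
}

msmraWarn <- function(fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c("msmra_warning", "warning", "condition")))
}

leakyRelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

leakyReluGrad <- function(pre, slope) {
  g <- array(1, dim(pre))
  g[pre < 0] <- slope
  g
}

## Row-wise softmax with the usual max-shift for stability.
softmaxRows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## Population standard deviation (divide by n, not n - 1).
popSD <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

isWholeNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < 1e-8
}
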