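#' Squared maximum mean discrepancy between two representation batches
#'
#' Kernel two-sample distance
#' \deqn{\mathrm{MMD}^2 = \|\tfrac1n\sum_x \phi(x) - \tfrac1m\sum_y \phi(y)\|_H^2}
#' expanded into kernel sums, with a sum of Gaussian kernels
#' \code{exp(-||x-y||^2 / (2 sigma_k^2))}. The default is the biased
#' V-statistic (always non-negative, stable on minibatches); set
#' \code{biased = FALSE} in the kernel config for the unbiased U-statistic.
#'
#' @param X,Y n x d and m x d numeric matrices (n, m >= 2 unless the kernel
#'   uses fixed bandwidths, which permits singleton oracle checks).
#' @param kernel a [KernelConfig-class].
#' @return The squared-MMD estimate (scalar).
#' @export
mmd2 <- function(X, Y, kernel = kernelConfig()) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1L)
  if (ncol(X) != ncol(Y))
    msmraStop("msmra_shape", "batch widths differ: %d vs %d", ncol(X), ncol(Y))
  if ((nrow(X) < 2L || nrow(Y) < 2L) && length(kernel@bandwidths) == 0L)
    msmraStop("msmra_insufficient_batch",
              "MMD needs >= 2 rows per side (got %d and %d)", nrow(X), nrow(Y))
  if (!kernel@biased && (nrow(X) < 2L || nrow(Y) < 2L))
    msmraStop("msmra_insufficient_batch",
              "the unbiased estimator needs >= 2 rows per side")
  .mmdKernelCpp(X, Y, kernel@bandwidths, kernel@numKernels,
                kernel@spreadFactor, kernel@biased, FALSE)$value
}

## mmd2 plus its gradient with respect to the rows of X and Y, used inside
## the training loop. Bandwidths are treated as constants (the usual
## convention for the median heuristic under SGD). Gradients are defined for
## the biased (V-statistic) estimator used during training.
mmd2WithGrad <- function(X, Y, kernel = kernelConfig()) {
  .mmdKernelCpp(X, Y, kernel@bandwidths, kernel@numKernels,
                kernel@spreadFactor, TRUE, TRUE)
}

#' Per-domain MMD: sum over the r parallel representations
#'
#' @param sourceReps,targetReps lists of r batches; element j of each must
#'   share its width (48/32/16 in the standard configuration).
#' @param kernel a [KernelConfig-class].
#' @return Sum over j of \code{mmd2(sourceReps[[j]], targetReps[[j]])}.
#' @export
mmdDomain <- function(sourceReps, targetReps, kernel = kernelConfig()) {
  if (length(sourceReps) != length(targetReps))
    msmraStop("msmra_representation_count",
              "source has %d representations, target has %d",
              length(sourceReps), length(targetReps))
  sum(vapply(seq_along(sourceReps), function(j)
    mmd2(sourceReps[[j]], targetReps[[j]], kernel), numeric(1)))
}

#' Total MMD over all source domains
#'
#' @param partitionReps list over the N domains; element i is a list with
#'   components \code{source} and \code{target}, each a list of r batches
#'   (the target representations differ per domain because the branches do).
#' @param kernel a [KernelConfig-class].
#' @return An [MMDEstimate-class] with per-representation, per-domain and
#'   total values.
#' @export
mmdTotal <- function(partitionReps, kernel = kernelConfig()) {
  if (length(partitionReps) == 0L)
    msmraStop("msmra_empty_input", "no source domains supplied")
  perRep <- lapply(partitionReps, function(d) {
    if (length(d$source) != length(d$target))
      msmraStop("msmra_representation_count",
                "source has %d representations, target has %d",
                length(d$source), length(d$target))
    vapply(seq_along(d$source), function(j)
      mmd2(d$source[[j]], d$target[[j]], kernel), numeric(1))
  })
  perDom <- vapply(perRep, sum, numeric(1))
  new("MMDEstimate", perRepresentation = perRep, perDomain = perDom,
      total = sum(perDom))
}
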