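#' EEGRecording: one subject-session unit of raw multichannel EEG
#'
#' Holds a channels x samples signal matrix (microvolts), its sampling rate,
#' half-open trial boundaries in samples, and one emotion label per trial.
#' Labels are integer class codes in \code{0..M-1}, matching the convention of
#' the public extracted-feature EEG releases.
#'
#' @slot signal numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot trials integer matrix with columns \code{start}, \code{end}; each row
#'   is the half-open sample interval \code{[start, end)} (1-based start) of
#'   one trial.
#' @slot labels integer vector, one label per trial, values in \code{0..M-1}.
#' @slot subjectId,sessionId identifiers used by the partitioning layer.
#'
#' @seealso [eegRecording()], [extractDEFeatures()]
#' @export
setClass("EEGRecording",
  representation(signal = "matrix", fs = "numeric", trials = "matrix",
                 labels = "integer", subjectId = "character",
                 sessionId = "character"))

setValidity("EEGRecording", function(object) {
  msgs <- character()
  if (!is.numeric(object@signal)) msgs <- c(msgs, "signal must be numeric")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msgs <- c(msgs, "fs must be a single positive number")
  tr <- object@trials
  if (ncol(tr) != 2L) msgs <- c(msgs, "trials must have two columns (start, end)")
  else {
    if (nrow(tr) != length(object@labels))
      msgs <- c(msgs, "one label per trial required")
    if (nrow(tr) > 0) {
      if (any(tr[, 1L] < 1L) || any(tr[, 2L] > ncol(object@signal) + 1L) ||
          any(tr[, 2L] <= tr[, 1L]))
        msgs <- c(msgs, "trial intervals must be non-empty and within the signal")
      o <- order(tr[, 1L])
      if (nrow(tr) > 1L && any(tr[o[-nrow(tr)], 2L] > tr[o[-1L], 1L]))
        msgs <- c(msgs, "trial intervals must be disjoint")
    }
  }
  if (length(object@labels) && any(object@labels < 0L))
    msgs <- c(msgs, "labels must be non-negative integer class codes")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EEGRecording
#'
#' @param signal channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param trials two-column matrix of half-open sample intervals
#'   \code{[start, end)}, one row per trial, or \code{NULL} for a single trial
#'   spanning the whole signal.
#' @param labels integer labels in \code{0..M-1}, one per trial.
#' @param subjectId,sessionId identifiers.
#' @return An [EEGRecording-class] object.
#' @export
eegRecording <- function(signal, fs, trials = NULL, labels = 0L,
                         subjectId = "s01", sessionId = "sess1") {
  if (is.null(trials))
    trials <- matrix(c(1L, ncol(signal) + 1L), nrow = 1L)
  trials <- matrix(as.integer(trials), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  new("EEGRecording", signal = signal, fs = fs, trials = trials,
      labels = as.integer(labels), subjectId = subjectId,
      sessionId = sessionId)
}

#' FeatureTensor: differential-entropy band features for one recording
#'
#' A windows x (channels * bands) matrix of differential-entropy features in
#' channel-major, band-minor column order (310 columns for the standard
#' 62-channel, 5-band layout), one label per window, plus provenance.
#'
#' @slot values numeric matrix, windows x features.
#' @slot layout character, flattening convention ("channel_major_band_minor").
#' @slot windowS window length in seconds.
#' @slot labels integer, one per window, values in \code{0..M-1}.
#' @slot normalized logical; TRUE once per-recording z-scoring has been applied.
#' @slot subjectId,sessionId identifiers.
#'
#' @seealso [featureTensor()], [normalizeFeatures()]
#' @export
setClass("FeatureTensor",
  representation(values = "matrix", layout = "character", windowS = "numeric",
                 labels = "integer", normalized = "logical",
                 subjectId = "character", sessionId = "character"))

setValidity("FeatureTensor", function(object) {
  msgs <- character()
  if (nrow(object@values) != length(object@labels))
    msgs <- c(msgs, "one label per window required")
  if (anyNA(object@labels))
    msgs <- c(msgs, "labels must not be NA")
  else if (length(object@labels) && any(object@labels < 0L))
    msgs <- c(msgs, "labels must be non-negative integer class codes")
  if (length(object@normalized) != 1L)
    msgs <- c(msgs, "normalized must be a single logical")
  if (isTRUE(object@normalized) && nrow(object@values) > 1L) {
    mu <- colMeans(object@values)
    v <- apply(object@values, 2L, var)
    ok <- abs(mu) < 1e-6 & (abs(v - 1) < 1e-6 | v < 1e-12)
    if (!all(ok))
      msgs <- c(msgs, "normalized tensor must have zero-mean unit-variance columns")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureTensor
#'
#' @param values windows x features numeric matrix.
#' @param labels integer labels, one per window.
#' @param windowS window length in seconds.
#' @param layout flattening convention of the feature axis.
#' @param normalized whether values are already per-column standardized.
#' @param subjectId,sessionId identifiers.
#' @return A [FeatureTensor-class] object.
#' @export
featureTensor <- function(values, labels, windowS = 1,
                          layout = "channel_major_band_minor",
                          normalized = FALSE,
                          subjectId = "s01", sessionId = "sess1") {
  new("FeatureTensor", values = values, labels = as.integer(labels),
      windowS = windowS, layout = layout, normalized = normalized,
      subjectId = subjectId, sessionId = sessionId)
}

#' SourceDomain: one two-recording source domain
#'
#' The two-partition grouping pools exactly two recordings into each source
#' domain, balancing marginal-distribution fidelity against model size. A
#' one-recording domain is permitted only as the explicit leftover of an odd
#' pairing (see [pairSources()]'s \code{allowSingleton}).
#'
#' @slot index 1-based domain index.
#' @slot members list of two (exceptionally one) [FeatureTensor-class]
#'   recordings.
#' @export
setClass("SourceDomain",
  representation(index = "integer", members = "list"))

setValidity("SourceDomain", function(object) {
  msgs <- character()
  if (!length(object@members) %in% 1:2)
    msgs <- c(msgs, "a source domain holds two (or exceptionally one) recordings")
  if (!all(vapply(object@members, is, logical(1), "FeatureTensor")))
    msgs <- c(msgs, "members must be FeatureTensor objects")
  else {
    w <- vapply(object@members, function(m) ncol(m@values), integer(1))
    if (length(unique(w)) != 1L)
      msgs <- c(msgs, "member feature widths must agree")
  }
  if (length(msgs)) msgs else TRUE
})

#' DomainPartition: N source domains plus one unlabeled target
#'
#' @slot sources list of [SourceDomain-class] objects.
#' @slot target one [FeatureTensor-class]; its labels are retained for
#'   evaluation only and are never used during training.
#' @slot scenario "cross_subject" or "cross_session".
#' @export
setClass("DomainPartition",
  representation(sources = "list", target = "FeatureTensor",
                 scenario = "character"))

setValidity("DomainPartition", function(object) {
  msgs <- character()
  if (length(object@sources) < 1L) msgs <- c(msgs, "at least one source domain required")
  if (!object@scenario %in% c("cross_subject", "cross_session"))
    msgs <- c(msgs, "scenario must be cross_subject or cross_session")
  ids <- unlist(lapply(object@sources, function(s)
    vapply(s@members, function(m) paste(m@subjectId, m@sessionId), character(1))))
  if (anyDuplicated(ids)) msgs <- c(msgs, "a recording appears in two source domains")
  tid <- paste(object@target@subjectId, object@target@sessionId)
  if (tid %in% ids) msgs <- c(msgs, "target recording also appears among sources")
  if (length(msgs)) msgs else TRUE
})

#' KernelConfig: multi-kernel Gaussian settings for the MMD estimator
#'
#' Defaults follow the deep-adaptation convention: five Gaussian kernels with
#' bandwidths geometrically spaced (factor 2) around the median pairwise
#' squared distance of the joint batch. A fixed bandwidth vector can be
#' supplied instead, which is what the closed-form oracle tests use.
#'
#' @slot family kernel family; only "gaussian" is implemented.
#' @slot numKernels number of kernels.
#' @slot spreadFactor multiplicative spacing between bandwidths.
#' @slot bandwidths optional fixed vector of squared bandwidths (sigma^2);
#'   overrides the median heuristic when non-empty.
#' @slot biased TRUE for the V-statistic estimator (default), FALSE for the
#'   unbiased U-statistic.
#' @export
setClass("KernelConfig",
  representation(family = "character", numKernels = "integer",
                 spreadFactor = "numeric", bandwidths = "numeric",
                 biased = "logical"))

setValidity("KernelConfig", function(object) {
  msgs <- character()
  if (object@family != "gaussian") msgs <- c(msgs, "only gaussian kernels are supported")
  if (object@numKernels < 1L) msgs <- c(msgs, "numKernels must be >= 1")
  if (object@numKernels > 1L && length(object@bandwidths) == 0L &&
      object@spreadFactor <= 1)
    msgs <- c(msgs, "spreadFactor must exceed 1 when numKernels > 1")
  if (length(object@bandwidths) && any(object@bandwidths <= 0))
    msgs <- c(msgs, "bandwidths must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @rdname KernelConfig-class
#' @param numKernels,spreadFactor,bandwidths,biased see slot documentation.
#' @return A [KernelConfig-class] object.
#' @export
kernelConfig <- function(numKernels = 5L, spreadFactor = 2,
                         bandwidths = numeric(0), biased = TRUE) {
  new("KernelConfig", family = "gaussian", numKernels = as.integer(numKernels),
      spreadFactor = spreadFactor, bandwidths = as.numeric(bandwidths),
      biased = biased)
}

#' MMDEstimate: per-representation, per-domain and total MMD losses
#'
#' @slot perRepresentation list of length N; element i is the numeric vector
#'   of the r squared-MMD values of domain i.
#' @slot perDomain numeric length N; \code{perDomain[i] = sum(perRepresentation[[i]])}.
#' @slot total sum of \code{perDomain}.
#' @export
setClass("MMDEstimate",
  representation(perRepresentation = "list", perDomain = "numeric",
                 total = "numeric"))

setValidity("MMDEstimate", function(object) {
  msgs <- character()
  eps <- 1e-8
  if (length(object@perRepresentation) != length(object@perDomain))
    msgs <- c(msgs, "perRepresentation and perDomain lengths differ")
  else {
    pd <- vapply(object@perRepresentation, sum, numeric(1))
    if (length(pd) && max(abs(pd - object@perDomain)) > 1e-9)
      msgs <- c(msgs, "perDomain must equal the per-representation sums")
  }
  if (abs(sum(object@perDomain) - object@total) > 1e-9)
    msgs <- c(msgs, "total must equal the per-domain sum")
  if (any(unlist(object@perRepresentation) < -eps))
    msgs <- c(msgs, "squared MMD values must be >= -1e-8")
  if (length(msgs)) msgs else TRUE
})

#' ModelConfig: architecture hyperparameters
#'
#' The default geometry is the standard 310-dimensional input (62 channels x
#' 5 bands), a shared three-layer extractor 310 -> 256 -> 128 -> 64, and
#' three per-domain representation branches of widths 48, 32 and 16 (each a
#' three-layer stack 64 -> 64 -> 64 -> width), concatenated to 96 and fed to
#' a per-domain softmax head. All hidden layers use a leaky rectifier.
#'
#' @slot inDim input feature width (310 in the standard layout).
#' @slot commonDims output widths of the shared extractor layers.
#' @slot branchDims output widths of the r parallel branches.
#' @slot branchHidden widths of the hidden layers inside each branch stack.
#' @slot nClasses number of emotion classes M.
#' @slot slope negative slope of the leaky rectifier.
#' @export
setClass("ModelConfig",
  representation(inDim = "integer", commonDims = "integer",
                 branchDims = "integer", branchHidden = "integer",
                 nClasses = "integer", slope = "numeric"))

setValidity("ModelConfig", function(object) {
  msgs <- character()
  if (object@inDim < 1L) msgs <- c(msgs, "inDim must be positive")
  if (length(object@commonDims) < 1L) msgs <- c(msgs, "need at least one common layer")
  if (length(object@branchDims) < 1L) msgs <- c(msgs, "need at least one branch")
  if (object@nClasses < 2L) msgs <- c(msgs, "need at least two classes")
  if (object@slope < 0) msgs <- c(msgs, "slope must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ModelConfig-class
#' @param inDim,commonDims,branchDims,branchHidden,nClasses,slope see slots.
#' @return A [ModelConfig-class] object.
#' @export
modelConfig <- function(inDim = 310L, commonDims = c(256L, 128L, 64L),
                        branchDims = c(48L, 32L, 16L),
                        branchHidden = c(64L, 64L), nClasses = 3L,
                        slope = 0.01) {
  new("ModelConfig", inDim = as.integer(inDim),
      commonDims = as.integer(commonDims), branchDims = as.integer(branchDims),
      branchHidden = as.integer(branchHidden), nClasses = as.integer(nClasses),
      slope = slope)
}

#' MSMRAModel: parameter container
#'
#' Parameters live in a nested list: \code{params$common} is a list of
#' \code{(W, b)} layers shared by every domain; \code{params$domains[[i]]}
#' holds that domain's \code{branches} (a list of r layer stacks) and its
#' classifier head \code{cls}. All N domains share the architecture but never
#' the parameters, so the gradient of one domain's classification loss is
#' identically zero with respect to another domain's branches and head.
#'
#' @slot config the [ModelConfig-class] used to build the parameters.
#' @slot nDomains number of source domains N.
#' @slot params nested parameter list (see Details).
#' @slot trained TRUE once [trainMSMRA()] has optimized the parameters.
#' @slot seed integer seed used for initialization.
#' @export
setClass("MSMRAModel",
  representation(config = "ModelConfig", nDomains = "integer",
                 params = "list", trained = "logical", seed = "integer"))

#' TrainConfig: optimization hyperparameters and ablation switches
#'
#' Defaults follow the published training recipe: Adam with initial learning
#' rate 0.01, batch size 256, 50 epochs, and the dynamic trade-off schedule
#' \code{alpha(i) = 2/(1 + exp(-10 i/epochs)) - 1} evaluated at the 0-based
#' epoch index so classification dominates early training.
#'
#' @slot lr learning rate.
#' @slot batchSize minibatch size (>= 4 so each MMD side has >= 2 rows).
#' @slot epochs number of epochs.
#' @slot alphaPerStep if TRUE the schedule advances per optimization step
#'   rather than per epoch.
#' @slot kernel [KernelConfig-class] for the MMD terms.
#' @slot normalize ablation switch: per-recording feature standardization.
#' @slot mdsfe ablation switch: FALSE collapses the multi-representation
#'   branches into a single 96-wide branch per domain.
#' @slot adapt ablation switch: FALSE pins alpha at 0 (no MMD alignment),
#'   leaving a pure multi-head source classifier.
#' @slot seed RNG seed controlling initialization and batch draws.
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", batchSize = "integer", epochs = "integer",
                 alphaPerStep = "logical", kernel = "KernelConfig",
                 normalize = "logical", mdsfe = "logical", adapt = "logical",
                 seed = "integer"))

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (object@epochs < 1L) msgs <- c(msgs, "epochs must be >= 1")
  if (object@batchSize < 4L) msgs <- c(msgs, "batchSize must be >= 4 (MMD needs >= 2 per side)")
  if (object@lr <= 0) msgs <- c(msgs, "lr must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TrainConfig-class
#' @param lr,batchSize,epochs,alphaPerStep,kernel,normalize,mdsfe,adapt,seed
#'   see slot documentation.
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(lr = 0.01, batchSize = 256L, epochs = 50L,
                        alphaPerStep = FALSE, kernel = kernelConfig(),
                        normalize = TRUE, mdsfe = TRUE, adapt = TRUE,
                        seed = 1L) {
  new("TrainConfig", lr = lr, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), alphaPerStep = alphaPerStep,
      kernel = kernel, normalize = normalize, mdsfe = mdsfe, adapt = adapt,
      seed = as.integer(seed))
}

#' SynthConfig: synthetic multi-domain generator settings
#'
#' The generator emulates a subject x session grid of feature recordings
#' with class-conditional Gaussian features under controlled covariate shift
#' (see [generateFeatureGrid()]). Defaults define the package's reference
#' synthetic study: a 5 subject x 2 session grid, 3 classes, 310 features,
#' 200 windows per recording, class-mean separation 3 sigma and domain-shift
#' magnitude 1.5 sigma.
#'
#' @slot nSubjects,nSessions grid dimensions.
#' @slot nClasses number of classes M (>= 2).
#' @slot dim feature width.
#' @slot windows windows per recording.
#' @slot deltaClass pairwise class-mean separation, in units of the noise SD.
#' @slot deltaDomain domain-shift magnitude, in units of the noise SD.
#' @slot noiseSd within-class noise standard deviation.
#' @slot seed RNG seed.
#' @export
setClass("SynthConfig",
  representation(nSubjects = "integer", nSessions = "integer",
                 nClasses = "integer", dim = "integer", windows = "integer",
                 deltaClass = "numeric", deltaDomain = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (object@nClasses < 2L) msgs <- c(msgs, "nClasses must be >= 2")
  if (any(c(object@deltaClass, object@deltaDomain) < 0))
    msgs <- c(msgs, "shift magnitudes must be >= 0")
  if (object@noiseSd <= 0) msgs <- c(msgs, "noiseSd must be positive")
  if (object@dim < object@nClasses)
    msgs <- c(msgs, "dim must be at least nClasses")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SynthConfig-class
#' @param nSubjects,nSessions,nClasses,dim,windows,deltaClass,deltaDomain,noiseSd,seed
#'   see slot documentation.
#' @return A [SynthConfig-class] object.
#' @export
synthConfig <- function(nSubjects = 5L, nSessions = 2L, nClasses = 3L,
                        dim = 310L, windows = 200L, deltaClass = 3,
                        deltaDomain = 1.5, noiseSd = 1, seed = 1L) {
  new("SynthConfig", nSubjects = as.integer(nSubjects),
      nSessions = as.integer(nSessions), nClasses = as.integer(nClasses),
      dim = as.integer(dim), windows = as.integer(windows),
      deltaClass = deltaClass, deltaDomain = deltaDomain, noiseSd = noiseSd,
      seed = as.integer(seed))
}
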