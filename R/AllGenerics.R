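#' Accessors for msmra data classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{featureValues} returns the windows x features matrix,
#' \code{windowLabels} the per-window labels, \code{nWindows} the window
#' count, \code{isNormalized} the standardization flag, and
#' \code{nDomains} the number of source domains of a partition or model.
#' \code{pooledFeatures} / \code{pooledLabels} stack the two member
#' recordings of a source domain.
#'
#' @param x an msmra object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))
#' @rdname accessors
#' @export
setGeneric("pooledFeatures", function(x) standardGeneric("pooledFeatures"))
#' @rdname accessors
#' @export
setGeneric("pooledLabels", function(x) standardGeneric("pooledLabels"))

#' @rdname accessors
setMethod("featureValues", "FeatureTensor", function(x) x@values)
#' @rdname accessors
setMethod("windowLabels", "FeatureTensor", function(x) x@labels)
#' @rdname accessors
setMethod("nWindows", "FeatureTensor", function(x) nrow(x@values))
#' @rdname accessors
setMethod("isNormalized", "FeatureTensor", function(x) x@normalized)

#' @rdname accessors
setMethod("pooledFeatures", "SourceDomain", function(x)
  do.call(rbind, lapply(x@members, featureValues)))
#' @rdname accessors
setMethod("pooledLabels", "SourceDomain", function(x)
  unlist(lapply(x@members, windowLabels), use.names = FALSE))
#' @rdname accessors
setMethod("nWindows", "SourceDomain", function(x)
  sum(vapply(x@members, nWindows, integer(1))))

#' @rdname accessors
setMethod("nDomains", "DomainPartition", function(x) length(x@sources))
#' @rdname accessors
setMethod("nDomains", "MSMRAModel", function(x) x@nDomains)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording %s/%s: %d channels x %d samples @ %g Hz, %d trials\n",
              object@subjectId, object@sessionId, nrow(object@signal),
              ncol(object@signal), object@fs, nrow(object@trials)))
})

setMethod("show", "FeatureTensor", function(object) {
  cat(sprintf("FeatureTensor %s/%s: %d windows x %d features (%s)%s\n",
              object@subjectId, object@sessionId, nrow(object@values),
              ncol(object@values), object@layout,
              if (object@normalized) ", normalized" else ""))
})

setMethod("show", "SourceDomain", function(object) {
  ids <- vapply(object@members, function(m)
    paste0(m@subjectId, "/", m@sessionId), character(1))
  cat(sprintf("SourceDomain %d: {%s}, %d pooled windows\n",
              object@index, paste(ids, collapse = ", "), nWindows(object)))
})

setMethod("show", "DomainPartition", function(object) {
  cat(sprintf("DomainPartition (%s): %d source domains, target %s/%s (%d windows)\n",
              object@scenario, length(object@sources),
              object@target@subjectId, object@target@sessionId,
              nWindows(object@target)))
})

setMethod("show", "MSMRAModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "MSMRAModel: %d -> %s common, %d domains x branches (%s) -> %d classes%s\n",
    cfg@inDim, paste(cfg@commonDims, collapse = " -> "), object@nDomains,
    paste(cfg@branchDims, collapse = ", "), cfg@nClasses,
    if (object@trained) " [trained]" else " [untrained]"))
})

setMethod("show", "MMDEstimate", function(object) {
  cat(sprintf("MMDEstimate: %d domains, total %.6g\n",
              length(object@perDomain), object@total))
})
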