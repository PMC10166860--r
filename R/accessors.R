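#' @include AllClasses.R
NULL

#' Extract the activity matrix
#' @param x a [RoiTraces-class] object.
#' @return numeric matrix, ROIs x frames.
#' @export
traceValues <- function(x) SummarizedExperiment::assay(x, "traces")

#' Sampling rate of a time-resolved object
#' @param x RoiTraces, TailTrace, GazeTrace, PhaseTrace or HeadingTrace.
#' @return rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "RoiTraces", function(x) S4Vectors::metadata(x)$rate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TailTrace", function(x) x@rate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "GazeTrace", function(x) x@rate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "PhaseTrace", function(x) x@rate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "HeadingTrace", function(x) x@rate)

#' ROI identifiers
#' @param x a RoiTraces or RpcEmbedding object.
#' @return character vector.
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))
#' @rdname roiIds
#' @export
setMethod("roiIds", "RoiTraces", function(x) rownames(x))
#' @rdname roiIds
#' @export
setMethod("roiIds", "RpcEmbedding", function(x) x@roiIds)

#' Per-ROI annotation table
#' @param x a [RoiTraces-class] object.
#' @return data.frame of ROI annotation (anatomy, ground-truth labels).
#' @export
roiInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' Is this trace matrix preprocessed (z-scored dF/F)?
#' @param x a [RoiTraces-class] object.
#' @return logical.
#' @export
isPreprocessed <- function(x) isTRUE(S4Vectors::metadata(x)$preprocessed)

#' Embedding coordinates and ring angles
#' @param x an [RpcEmbedding-class] object.
#' @return `rpcCoords`: n x 2 matrix; `ringAlpha`: named numeric of angles.
#' @export
rpcCoords <- function(x) x@coords

#' @rdname rpcCoords
#' @export
ringAlpha <- function(x) stats::setNames(x@alpha, x@roiIds)

#' Phase accessors
#' @param x a [PhaseTrace-class] object.
#' @return numeric vector per frame.
#' @export
wrappedPhase <- function(x) x@wrapped

#' @rdname wrappedPhase
#' @export
unwrappedPhase <- function(x) x@unwrapped

#' @rdname wrappedPhase
#' @export
phaseVectorNorm <- function(x) x@vectorNorm

#' Heading values
#' @param x a [HeadingTrace-class] object.
#' @return radians per frame.
#' @export
headingValues <- function(x) x@heading

#' Selected ring ROI ids
#' @param x a [RingSelection-class] object.
#' @return character vector.
#' @export
selectedIds <- function(x) x@selectedIds

#' Skeleton node table
#' @param x a [Skeleton-class] object.
#' @return data.frame with id, parent, x, y, z, radius, compartment.
#' @export
skeletonNodes <- function(x) x@nodes

#' Ground truth of a synthetic session
#' @param x a [SyntheticSession-class] object.
#' @return the [GroundTruth-class] object.
#' @export
sessionTruth <- function(x) x@truth

#' @rdname sessionTruth
#' @export
sessionTraces <- function(x) x@traces

#' @rdname sessionTruth
#' @export
sessionTail <- function(x) x@tail

#' @rdname sessionTruth
#' @export
sessionGaze <- function(x) x@gaze

#' @rdname sessionTruth
#' @export
sessionParamsOf <- function(x) x@params

setMethod("show", "RoiTraces", function(object) {
  cat(sprintf("RoiTraces: %d ROIs x %d frames @ %.3g Hz (%s)\n",
              nrow(object), ncol(object), samplingRate(object),
              if (isPreprocessed(object)) "preprocessed" else "raw"))
})

setMethod("show", "PhaseTrace", function(object) {
  cat(sprintf("PhaseTrace: %d frames @ %.3g Hz, unwrapped span %.2f rad\n",
              length(object@wrapped), object@rate,
              diff(range(object@unwrapped))))
})

setMethod("show", "RpcEmbedding", function(object) {
  cat(sprintf(
    "RpcEmbedding: %d ROIs on the unit circle; rotation %.3f rad%s; anchor misfits (%.4f, %.4f) rad\n",
    nrow(object@coords), object@transform$rotation,
    if (isTRUE(object@transform$reflection)) " + reflection" else "",
    object@anchorAngles[1], object@anchorAngles[2]))
})

setMethod("show", "RingSelection", function(object) {
  cat(sprintf("RingSelection: %d selected, %d excluded (threshold %.2f, quality %.3f)\n",
              length(object@selectedIds), length(object@excludedIds),
              object@thresholdUsed, object@quality))
})

setMethod("show", "SyntheticSession", function(object) {
  p <- object@params
  cat(sprintf(
    "SyntheticSession: %d ring + %d distractor ROIs, %.0f s @ %.3g Hz, %d swims (seed %d)\n",
    sum(roiInfo(object@traces)$is_ring),
    sum(!roiInfo(object@traces)$is_ring), p@durationS, p@imagingRateHz,
    nrow(object@truth@swimEvents), as.integer(p@seed)))
})

setMethod("show", "BumpProfile", function(object) {
  cat(sprintf("BumpProfile: %d bins, FWHM %.3f rad\n",
              length(object@bins), object@fwhm))
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton %s: %d nodes (%s)\n", object@neuronId,
              nrow(object@nodes),
              paste(sprintf("%s=%d", names(table(object@nodes$compartment)),
                            as.integer(table(object@nodes$compartment))),
                    collapse = ", ")))
})
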