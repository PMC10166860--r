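#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#' @importFrom S4Vectors metadata DataFrame
NULL

# ---------------------------------------------------------------------------
# RoiTraces: ROI x frame activity matrix with anatomy and sampling rate.
# Conventions used throughout the package (documented once here):
#   * anatomical coordinates in rowData: `lr` (left-right, positive = fish's
#     left), `rc` (rostro-caudal, positive = rostral), `dv` (dorso-ventral),
#     all micrometres relative to the aHB reference point;
#   * anatomical angle in the horizontal plane: atan2(lr, -rc), i.e. caudal
#     = 0, left = +pi/2, right = -pi/2, increasing clockwise seen from above;
#   * laterality index > 0 means a rightward swim; the integrated heading
#     increases with right swims while the network phase decreases.
# ---------------------------------------------------------------------------

#' ROI activity traces
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"traces"`
#' (ROIs x frames), ROI anatomy in `rowData` and the sampling rate plus a
#' `preprocessed` flag in `metadata`. Raw fluorescence and preprocessed
#' (z-scored dF/F) matrices share this container.
#'
#' @export
setClass("RoiTraces", contains = "SummarizedExperiment")

setValidity("RoiTraces", function(object) {
  msg <- character()
  if (!"traces" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'traces' is required")
  } else if (!is.numeric(SummarizedExperiment::assay(object, "traces"))) {
    msg <- c(msg, "assay 'traces' must be numeric")
  }
  rate <- S4Vectors::metadata(object)$rate
  if (is.null(rate) || !is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    msg <- c(msg, "metadata$rate must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RoiTraces object
#'
#' @param values numeric matrix, ROIs x frames.
#' @param rate sampling rate in Hz.
#' @param roi optional data.frame of per-ROI annotation (anatomical
#'   coordinates `lr`, `rc`, `dv` in micrometres, `is_ring`, `true_alpha`,
#'   ...); row order matches `values`.
#' @param roiIds character ROI identifiers; default from rownames or R1..Rn.
#' @param preprocessed logical flag: TRUE once traces are z-scored dF/F.
#' @return a [RoiTraces-class] object.
#' @export
RoiTraces <- function(values, rate, roi = NULL, roiIds = NULL,
                      preprocessed = FALSE) {
  values <- as.matrix(values)
  if (is.null(roiIds)) {
    roiIds <- if (!is.null(rownames(values))) rownames(values) else
      sprintf("R%03d", seq_len(nrow(values)))
  }
  rownames(values) <- roiIds
  rd <- if (is.null(roi)) S4Vectors::DataFrame(row.names = roiIds) else {
    rd0 <- S4Vectors::DataFrame(roi)
    rownames(rd0) <- roiIds
    rd0
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(traces = values), rowData = rd,
    metadata = list(rate = rate, preprocessed = isTRUE(preprocessed)))
  methods::new("RoiTraces", se)
}

# ---------------------------------------------------------------------------

#' Tail-angle trace
#'
#' Tail angle in radians per frame (difference between the mean angle of the
#' first two and the last two tracked tail segments) at `rate` Hz.
#'
#' @slot angle numeric, radians.
#' @slot rate sampling rate, Hz.
#' @export
setClass("TailTrace", representation(angle = "numeric", rate = "numeric"),
         validity = function(object) {
           if (length(object@rate) != 1 || object@rate <= 0)
             return("rate must be a single positive number")
           if (any(!is.finite(object@angle)))
             return("tail angle must be finite")
           TRUE
         })

#' @rdname TailTrace-class
#' @param angle,rate see slots.
#' @export
TailTrace <- function(angle, rate) methods::new("TailTrace", angle = angle, rate = rate)

#' Gaze trace
#'
#' Gaze direction (mean of the two eye angles) with detected saccade times.
#'
#' @slot angle radians per frame.
#' @slot rate Hz.
#' @slot saccadeTimes seconds.
#' @export
setClass("GazeTrace",
         representation(angle = "numeric", rate = "numeric",
                        saccadeTimes = "numeric"),
         validity = function(object) {
           if (length(object@rate) != 1 || object@rate <= 0)
             return("rate must be a single positive number")
           if (any(!is.finite(object@angle))) return("gaze angle must be finite")
           TRUE
         })

#' @rdname GazeTrace-class
#' @param angle,rate,saccadeTimes see slots.
#' @export
GazeTrace <- function(angle, rate, saccadeTimes = numeric()) {
  methods::new("GazeTrace", angle = angle, rate = rate,
               saccadeTimes = saccadeTimes)
}

setClassUnion("GazeTraceOrNULL", c("GazeTrace", "NULL"))

# ---------------------------------------------------------------------------

#' Circle fit
#'
#' @slot center numeric length-2.
#' @slot radius positive scalar.
#' @export
setClass("CircleFit", representation(center = "numeric", radius = "numeric"),
         validity = function(object) {
           if (length(object@center) != 2) return("center must have length 2")
           if (length(object@radius) != 1 || !is.finite(object@radius) ||
               object@radius <= 0) return("radius must be a positive number")
           TRUE
         })

#' Rotated-PC circular embedding
#'
#' Per-ROI coordinates on the unit circle of rotated principal components,
#' with the ring angle alpha in (-pi, pi] under the caudal-zero,
#' clockwise-positive convention (left = +pi/2, right = -pi/2).
#'
#' @slot coords n x 2 matrix of unit-circle-normalized rPC coordinates.
#' @slot alpha radians per ROI.
#' @slot transform list recording center, radius, rotation (rad) and
#'   reflection applied during alignment.
#' @slot anchorAngles residual misfits (theta1, theta2) of the rostral and
#'   rightward anchor vectors after alignment, radians.
#' @slot roiIds character identifiers.
#' @export
setClass("RpcEmbedding",
         representation(coords = "matrix", alpha = "numeric",
                        transform = "list", anchorAngles = "numeric",
                        roiIds = "character"),
         validity = function(object) {
           if (ncol(object@coords) != 2) return("coords must be n x 2")
           if (nrow(object@coords) != length(object@alpha))
             return("alpha length must match coords rows")
           if (length(object@roiIds) != nrow(object@coords))
             return("roiIds length must match coords rows")
           TRUE
         })

#' Decoded network phase
#'
#' @slot wrapped radians in (-pi, pi] per frame.
#' @slot unwrapped cumulative phase, radians per frame.
#' @slot vectorNorm per-frame magnitude of the population vector (decoding
#'   confidence).
#' @slot rate Hz.
#' @export
setClass("PhaseTrace",
         representation(wrapped = "numeric", unwrapped = "numeric",
                        vectorNorm = "numeric", rate = "numeric"),
         validity = function(object) {
           n <- length(object@wrapped)
           if (length(object@unwrapped) != n || length(object@vectorNorm) != n)
             return("wrapped, unwrapped and vectorNorm must share length")
           if (n > 1 && max(abs(circDist(object@wrapped, object@unwrapped))) > 1e-6)
             return("wrapped must equal unwrapped modulo 2*pi")
           TRUE
         })

#' Bump activity profile
#'
#' Phase-zeroed population activity over 100 ring-angle bins.
#'
#' @slot bins bin-center angles spanning (-pi, pi].
#' @slot mean,sd activity per bin, over frames.
#' @slot fwhm full width at half maximum, radians.
#' @slot raw list with the non-interpolated (alpha-sorted, nearest-bin
#'   shifted) consistency-check profile: `angles`, `mean`.
#' @export
setClass("BumpProfile",
         representation(bins = "numeric", mean = "numeric", sd = "numeric",
                        fwhm = "numeric", raw = "list"),
         validity = function(object) {
           if (length(object@bins) != length(object@mean) ||
               length(object@bins) != length(object@sd))
             return("bins, mean and sd must share length")
           TRUE
         })

#' Ring-ROI selection
#'
#' @slot selectedIds,excludedIds ROI identifiers.
#' @slot thresholdUsed anticorrelation threshold applied.
#' @slot quality ring-quality score, 1 - CV of PC projection radii.
#' @slot exclusionReason named character, reason per excluded ROI.
#' @export
setClass("RingSelection",
         representation(selectedIds = "character", thresholdUsed = "numeric",
                        quality = "numeric", excludedIds = "character",
                        exclusionReason = "character"),
         validity = function(object) {
           if (length(intersect(object@selectedIds, object@excludedIds)) > 0)
             return("selected and excluded ROI sets must be disjoint")
           TRUE
         })

#' Integrated heading trace
#'
#' Cumulative sum of swim laterality indices, held constant between swims.
#'
#' @slot heading radians per frame.
#' @slot rate Hz.
#' @export
setClass("HeadingTrace",
         representation(heading = "numeric", rate = "numeric"))

#' Neuron skeleton
#'
#' SWC-style node tree in a midline-referenced frame (x = coronal/frontal
#' axis with `midlineX` the midline coordinate, y = anteroposterior,
#' z = dorsoventral; micrometres).
#'
#' @slot nodes data.frame with columns id, parent, x, y, z, radius,
#'   compartment (soma/dendrite/axon/unlabeled).
#' @slot midlineX micrometres.
#' @slot neuronId identifier.
#' @export
setClass("Skeleton",
         representation(nodes = "data.frame", midlineX = "numeric",
                        neuronId = "character"))

# ---------------------------------------------------------------------------

#' Parameters of a synthetic ring-attractor session
#'
#' Defaults define the reference study conditions used across the test suite:
#' 80 ring neurons imaged at 5 Hz for 600 s, raised-cosine tuning of unit
#' amplitude, GCaMP6s-like 1.8 s indicator decay, additive noise sd 0.15,
#' Poisson swim bouts at 0.1 Hz with a symmetric trimodal laterality mixture,
#' tail sampled at 400 Hz, 30% distractor ROIs.
#'
#' @slot nNeurons ring ROI count.
#' @slot durationS session length, seconds.
#' @slot imagingRateHz,behaviorRateHz sampling rates, Hz.
#' @slot tuningShape "raised_cosine" or "von_mises".
#' @slot tuningKappa von Mises concentration (used only for von_mises).
#' @slot amplitude tuning peak, activity units.
#' @slot noiseSd additive Gaussian noise sd, activity units.
#' @slot calciumTauS indicator decay time constant, seconds.
#' @slot swimRateHz Poisson bout rate, Hz.
#' @slot lateralityCentralSd,lateralitySideMean,lateralitySideSd,lateralityCentralWeight
#'   symmetric trimodal mixture of the laterality index (central mean fixed
#'   at 0; the two side components mirror each other and share weight
#'   (1 - central weight)/2).
#' @slot phaseGain radians of bump rotation per radian of laterality index;
#'   positive values make left swims (laterality < 0) increase the phase.
#' @slot distractorFraction fraction of total ROIs that are non-ring.
#' @slot motorLockedFraction fraction of distractors carrying a motor-locked
#'   signal rather than pure noise.
#' @slot baselineF raw fluorescence baseline, a.u.
#' @slot bleachFraction fractional linear decay of baseline over the session.
#' @slot boutCarrierHz,boutAmplitude,boutDurationRangeS,boutRefractoryS,tailNoiseSd
#'   tail kinematics of a rendered bout (decaying sinusoid).
#' @slot ringRadiusUm,ringEllipseRatio,positionJitterUm anatomical ring layout.
#' @slot gazeSaccadeRateHz,gazeSaccadeSd piecewise-constant gaze generator;
#'   rate 0 disables the gaze trace.
#' @slot seed RNG seed.
#' @export
setClass("SessionParams",
  representation(
    nNeurons = "numeric", durationS = "numeric", imagingRateHz = "numeric",
    behaviorRateHz = "numeric", tuningShape = "character",
    tuningKappa = "numeric", amplitude = "numeric", noiseSd = "numeric",
    calciumTauS = "numeric", swimRateHz = "numeric",
    lateralityCentralSd = "numeric", lateralitySideMean = "numeric",
    lateralitySideSd = "numeric", lateralityCentralWeight = "numeric",
    phaseGain = "numeric", distractorFraction = "numeric",
    motorLockedFraction = "numeric", baselineF = "numeric",
    bleachFraction = "numeric", boutCarrierHz = "numeric",
    boutAmplitude = "numeric", boutDurationRangeS = "numeric",
    boutRefractoryS = "numeric", tailNoiseSd = "numeric",
    ringRadiusUm = "numeric", ringEllipseRatio = "numeric",
    positionJitterUm = "numeric", gazeSaccadeRateHz = "numeric",
    gazeSaccadeSd = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nNeurons < 8) msg <- c(msg, "nNeurons must be >= 8")
    for (s in c("durationS", "imagingRateHz", "behaviorRateHz"))
      if (methods::slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
    if (!object@tuningShape %in% c("raised_cosine", "von_mises"))
      msg <- c(msg, "tuningShape must be raised_cosine or von_mises")
    if (object@swimRateHz < 0) msg <- c(msg, "swimRateHz must be >= 0")
    if (object@lateralityCentralWeight < 0 || object@lateralityCentralWeight > 1)
      msg <- c(msg, "lateralityCentralWeight must be in [0, 1]")
    if (object@distractorFraction < 0 || object@distractorFraction >= 1)
      msg <- c(msg, "distractorFraction must be in [0, 1)")
    if (length(object@boutDurationRangeS) != 2 ||
        diff(object@boutDurationRangeS) < 0)
      msg <- c(msg, "boutDurationRangeS must be an increasing length-2 range")
    if (length(msg)) msg else TRUE
  })

#' @rdname SessionParams-class
#' @param ... named slot overrides, see slot documentation.
#' @return a validated [SessionParams-class] object.
#' @export
sessionParams <- function(...) {
  p <- methods::new("SessionParams",
    nNeurons = 80, durationS = 600, imagingRateHz = 5, behaviorRateHz = 400,
    tuningShape = "raised_cosine", tuningKappa = 2, amplitude = 1,
    noiseSd = 0.15, calciumTauS = 1.8, swimRateHz = 0.1,
    lateralityCentralSd = 0.1, lateralitySideMean = 0.6,
    lateralitySideSd = 0.15, lateralityCentralWeight = 0.3,
    phaseGain = 1, distractorFraction = 0.3, motorLockedFraction = 0.5,
    baselineF = 100, bleachFraction = 0.05, boutCarrierHz = 25,
    boutAmplitude = 1, boutDurationRangeS = c(0.15, 0.3),
    boutRefractoryS = 0.5, tailNoiseSd = 0.005, ringRadiusUm = 30,
    ringEllipseRatio = 1, positionJitterUm = 1.5, gazeSaccadeRateHz = 0,
    gazeSaccadeSd = 0.2, seed = 1)
  override <- list(...)
  bad <- setdiff(names(override), methods::slotNames("SessionParams"))
  if (length(bad)) stop("unknown SessionParams fields: ", paste(bad, collapse = ", "))
  for (nm in names(override)) methods::slot(p, nm) <- override[[nm]]
  methods::validObject(p)
  p
}

#' Ground truth of a synthetic session
#'
#' @slot truePhase radians per imaging frame (unwrapped).
#' @slot trueHeading radians per behavior frame.
#' @slot trueAlpha radians per ring ROI.
#' @slot swimEvents data.frame of generated swims (onset_s, offset_s,
#'   laterality, swim_class).
#' @export
setClass("GroundTruth",
         representation(truePhase = "numeric", trueHeading = "numeric",
                        trueAlpha = "numeric", swimEvents = "data.frame"))

#' Synthetic ring-attractor session
#'
#' @slot traces raw fluorescence [RoiTraces-class] (feed to [computeDff()]).
#' @slot signal the rendered calcium activity (output of [renderCalcium()],
#'   before the raw-fluorescence wrapping), for decoder round-trip checks.
#' @slot tail [TailTrace-class].
#' @slot gaze [GazeTrace-class] or NULL.
#' @slot truth [GroundTruth-class].
#' @slot params [SessionParams-class].
#' @export
setClass("SyntheticSession",
         representation(traces = "RoiTraces", signal = "RoiTraces",
                        tail = "TailTrace",
                        gaze = "GazeTraceOrNULL", truth = "GroundTruth",
                        params = "SessionParams"))
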