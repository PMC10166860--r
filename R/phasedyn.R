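#' @include AllClasses.R utils-circular.R
NULL

#' Unwrap a wrapped phase series
#'
#' Removes every discontinuity at +-pi by adding offsets 2*pi*k; the first
#' sample is preserved.
#'
#' @param wrapped radians.
#' @return unwrapped radians, same length.
#' @export
unwrapPhase <- function(wrapped) {
  if (length(wrapped) < 2) return(wrapped)
  wrapped[1] + cumsum(c(0, wrapToPi(diff(wrapped))))
}

#' Decode the network phase by population-vector averaging
#'
#' Computes v(t) = (1/n) sum_i f_i(t) rPC_i where rPC_i are the unit-circle
#' embedding coordinates and f_i(t) the activity after (a) clipping each
#' ROI's trace to its 2nd/98th percentiles and (b) subtracting the
#' across-ROI mean at every frame, enforcing sum_i f_i(t) = 0. The wrapped
#' phase is the angle of v(t) under the alpha convention (caudal = 0,
#' left = +pi/2); the unwrapped phase removes the 2*pi discontinuities.
#'
#' @param traces a preprocessed [RoiTraces-class] covering the embedding ROIs.
#' @param embedding an [RpcEmbedding-class].
#' @param clipQuantiles lower/upper clipping quantiles; NULL disables.
#' @param clipMode `"roi"` (default): quantiles per ROI over the recording;
#'   `"frame"`: quantiles across ROIs at each frame.
#' @return a [PhaseTrace-class].
#' @export
computePhase <- function(traces, embedding, clipQuantiles = c(0.02, 0.98),
                         clipMode = c("roi", "frame")) {
  clipMode <- match.arg(clipMode)
  ids <- embedding@roiIds
  if (!all(ids %in% rownames(traces))) {
    stop("embedding covers ROIs missing from the trace matrix")
  }
  f <- traceValues(traces)[ids, , drop = FALSE]
  if (!is.null(clipQuantiles)) {
    if (clipMode == "roi") {
      for (i in seq_len(nrow(f))) {
        q <- stats::quantile(f[i, ], clipQuantiles, names = FALSE)
        f[i, ] <- pmin(pmax(f[i, ], q[1]), q[2])
      }
    } else {
      for (t in seq_len(ncol(f))) {
        q <- stats::quantile(f[, t], clipQuantiles, names = FALSE)
        f[, t] <- pmin(pmax(f[, t], q[1]), q[2])
      }
    }
  }
  f <- sweep(f, 2, colMeans(f))
  v <- t(embedding@coords) %*% f / nrow(f)    # 2 x frames
  vnorm <- sqrt(colSums(v^2))
  if (mean(vnorm < 1e-10) > 0.5) {
    warning("population vector norm is below tolerance for > 50% of frames: phase ill-defined")
  }
  wrapped <- wrapToPi(atan2(v[2, ], v[1, ]))
  methods::new("PhaseTrace", wrapped = as.numeric(wrapped),
               unwrapped = unwrapPhase(as.numeric(wrapped)),
               vectorNorm = as.numeric(vnorm), rate = samplingRate(traces))
}

# periodic linear interpolation of (alpha, value) onto a grid of angles
.interpCircular <- function(alpha, values, gridAngles) {
  ord <- order(alpha)
  a <- alpha[ord]
  v <- values[ord]
  aPad <- c(a[length(a)] - 2 * pi, a, a[1] + 2 * pi)
  vPad <- c(v[length(v)], v, v[1])
  stats::approx(aPad, vPad, xout = gridAngles, rule = 2)$y
}

#' Phase-zeroed average activity profile of the bump
#'
#' Interpolates the population activity over the ring angle onto 100 bins
#' spanning (-pi, pi], circularly shifts each frame by the decoded phase so
#' the bump peak sits at the profile center, and averages over frames. A
#' non-interpolated consistency check (alpha-sorted raw matrix shifted by
#' the nearest ROI position) is stored in the `raw` slot.
#'
#' @param traces preprocessed [RoiTraces-class] (>= 8 ROIs in the embedding).
#' @param embedding an [RpcEmbedding-class].
#' @param phase the [PhaseTrace-class] computed from the same session.
#' @param nBins bin count for the interpolated profile.
#' @return a [BumpProfile-class].
#' @export
phaseZeroedProfile <- function(traces, embedding, phase, nBins = 100) {
  ids <- embedding@roiIds
  if (length(ids) < 8) stop("need at least 8 ROIs for a reliable interpolation")
  f <- traceValues(traces)[ids, , drop = FALSE]
  alpha <- embedding@alpha
  binW <- 2 * pi / nBins
  centers <- -pi + binW * (seq_len(nBins) - 0.5)
  nFrames <- ncol(f)
  mat <- matrix(NA_real_, nBins, nFrames)
  wrapped <- phase@wrapped
  for (t in seq_len(nFrames)) {
    prof <- .interpCircular(alpha, f[, t], centers)
    s <- round(wrapped[t] / binW)
    mat[, t] <- prof[1 + ((seq_len(nBins) - 1 + s) %% nBins)]
  }
  m <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  # relative angle of each output bin with respect to the bump peak
  relAngles <- centers
  fw <- estimateFwhm(m, relAngles)
  # raw-sorted variant: shift rows by the ROI index nearest the phase
  ordA <- order(alpha)
  aS <- alpha[ordA]
  fS <- f[ordA, , drop = FALSE]
  nR <- length(aS)
  rawMat <- matrix(NA_real_, nR, nFrames)
  centerIdx <- which.min(abs(aS))      # ROI closest to alpha = 0
  for (t in seq_len(nFrames)) {
    k <- which.min(abs(circDist(aS, wrapped[t])))
    s <- k - centerIdx
    rawMat[, t] <- fS[1 + ((seq_len(nR) - 1 + s) %% nR), t]
  }
  rawMean <- rowMeans(rawMat)
  rawAngles <- wrapToPi(aS - aS[centerIdx])
  methods::new("BumpProfile", bins = centers, mean = m, sd = sdv, fwhm = fw,
               raw = list(angles = rawAngles, mean = rawMean))
}

#' Full width at half maximum of a circular activity profile
#'
#' Baseline is the profile minimum; the half level is baseline +
#' (max - baseline)/2; the two crossings flanking the peak are located by
#' linear interpolation on the circle and the FWHM is the angular distance
#' between them through the peak.
#'
#' @param profile activity per bin.
#' @param bins bin-center angles, radians, ascending over one cycle.
#' @param tol minimum peak-to-baseline range; below it the profile is
#'   considered flat.
#' @return FWHM in radians, in (0, 2*pi).
#' @export
estimateFwhm <- function(profile, bins, tol = 1e-9) {
  n <- length(profile)
  stopifnot(length(bins) == n)
  lo <- min(profile)
  hi <- max(profile)
  if (hi - lo < tol) stop("no bump: profile is flat")
  half <- lo + (hi - lo) / 2
  pk <- which.max(profile)
  cross <- function(dir) {
    # walk from the peak in direction dir until the profile dips below half
    prev <- pk
    for (step in seq_len(n - 1)) {
      cur <- 1 + ((pk - 1 + dir * step) %% n)
      if (profile[cur] < half) {
        a1 <- bins[prev]; a2 <- bins[cur]
        da <- wrapToPi(a2 - a1)
        frac <- (profile[prev] - half) / (profile[prev] - profile[cur])
        return(wrapToPi(a1 + frac * da))
      }
      prev <- cur
    }
    stop("no bump: profile never falls below the half level")
  }
  right <- cross(+1)
  left <- cross(-1)
  width <- (right - left) %% (2 * pi)
  if (width == 0) width <- 2 * pi
  width
}

#' Single-neuron tuning curves over the network phase
#'
#' Per-ROI mean activity binned by the wrapped network phase, with a FWHM
#' estimate per curve. Empty phase bins are marked missing and interpolated
#' circularly before the FWHM computation; a curve with more than half of
#' its bins missing gets a FWHM of NA.
#'
#' @param traces preprocessed [RoiTraces-class].
#' @param phase a [PhaseTrace-class] on the same frames.
#' @param nBins phase bin count.
#' @return list with `phaseBins` (centers), `curves` (ROIs x bins matrix) and
#'   `fwhm` (named per-ROI; NA where undefined).
#' @export
tuningCurves <- function(traces, phase, nBins = 36) {
  f <- traceValues(traces)
  stopifnot(ncol(f) == length(phase@wrapped))
  if (diff(range(phase@unwrapped)) < 2 * pi) {
    warning("less than one full phase revolution: tuning curves may be incomplete")
  }
  binW <- 2 * pi / nBins
  centers <- -pi + binW * (seq_len(nBins) - 0.5)
  idx <- pmin(nBins, pmax(1, floor((phase@wrapped + pi) / binW) + 1))
  curves <- matrix(NA_real_, nrow(f), nBins,
                   dimnames = list(rownames(f), NULL))
  for (b in seq_len(nBins)) {
    sel <- idx == b
    if (any(sel)) curves[, b] <- rowMeans(f[, sel, drop = FALSE])
  }
  fwhm <- vapply(seq_len(nrow(f)), function(i) {
    y <- curves[i, ]
    miss <- is.na(y)
    if (mean(miss) > 0.5) return(NA_real_)
    if (any(miss)) y <- .interpCircular(centers[!miss], y[!miss], centers)
    tryCatch(estimateFwhm(y, centers), error = function(e) NA_real_)
  }, numeric(1))
  list(phaseBins = centers, curves = curves,
       fwhm = stats::setNames(fwhm, rownames(f)))
}
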