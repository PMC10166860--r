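#' @include AllClasses.R
NULL

# centered rolling mean with truncated edge windows, O(n) via cumsum
.rollMeanCentered <- function(x, w) {
  n <- length(x)
  h <- floor(w / 2)
  cs <- c(0, cumsum(x))
  hi <- pmin(n, seq_len(n) + h)
  lo <- pmax(1, seq_len(n) - h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Compute dF/F with a rolling baseline
#'
#' Baseline B_i(t) is the average fluorescence in a centered rolling window
#' (default 900 s, truncated at the edges), which removes slow bleaching
#' trends; dF/F_i(t) = (F_i(t) - B_i(t)) / B_i(t).
#'
#' @param raw a [RoiTraces-class] of raw fluorescence.
#' @param baselineWindowS baseline window length, seconds.
#' @param statistic baseline statistic: `"mean"` (default) or
#'   `"percentile"` (rolling quantile, see `percentile`).
#' @param percentile quantile in (0, 1) used when `statistic = "percentile"`.
#' @return a [RoiTraces-class] holding the dF/F matrix (not yet z-scored).
#' @export
computeDff <- function(raw, baselineWindowS = 900, statistic = c("mean", "percentile"),
                       percentile = 0.3) {
  statistic <- match.arg(statistic)
  values <- traceValues(raw)
  rate <- samplingRate(raw)
  w <- max(2, round(baselineWindowS * rate))
  out <- values
  for (i in seq_len(nrow(values))) {
    b <- if (statistic == "mean") {
      .rollMeanCentered(values[i, ], w)
    } else {
      n <- ncol(values)
      h <- floor(w / 2)
      vapply(seq_len(n), function(t) {
        stats::quantile(values[i, max(1, t - h):min(n, t + h)], percentile,
                        names = FALSE)
      }, numeric(1))
    }
    if (any(b <= 0)) {
      stop(sprintf("non-positive baseline for ROI '%s': raw fluorescence must be positive",
                   rownames(values)[i]))
    }
    out[i, ] <- (values[i, ] - b) / b
  }
  RoiTraces(out, rate = rate, roi = roiInfo(raw), roiIds = rownames(values),
            preprocessed = FALSE)
}

#' Median-filter and z-score dF/F traces
#'
#' Per-ROI running-median smoothing followed by z-scoring, so every trace is
#' centered on zero with unit standard deviation. Zero-variance ROIs are
#' dropped with a warning.
#'
#' @param dff a [RoiTraces-class] (or plain matrix) of dF/F values.
#' @param medianKernelFrames odd kernel width in frames; 1 disables smoothing.
#' @param rate sampling rate, required only when `dff` is a matrix.
#' @return a preprocessed [RoiTraces-class].
#' @export
denoiseZscore <- function(dff, medianKernelFrames = 3, rate = NULL) {
  if (is.matrix(dff)) {
    stopifnot(!is.null(rate))
    dff <- RoiTraces(dff, rate = rate)
  }
  k <- medianKernelFrames
  if (k < 1 || k %% 2 != 1) stop("medianKernelFrames must be odd and >= 1")
  values <- traceValues(dff)
  if (k > 1) {
    for (i in seq_len(nrow(values))) {
      values[i, ] <- stats::runmed(values[i, ], k, endrule = "median")
    }
  }
  sds <- apply(values, 1, stats::sd)
  if (all(sds == 0)) stop("all traces are constant: nothing to analyze")
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance ROI(s): %s", sum(sds == 0),
                    paste(rownames(values)[sds == 0], collapse = ", ")))
    keepRoi <- sds > 0
    values <- values[keepRoi, , drop = FALSE]
    roi <- roiInfo(dff)[keepRoi, , drop = FALSE]
  } else {
    roi <- roiInfo(dff)
  }
  values <- (values - rowMeans(values)) / apply(values, 1, stats::sd)
  RoiTraces(values, rate = samplingRate(dff), roi = roi,
            roiIds = rownames(values), preprocessed = TRUE)
}

#' Full trace preprocessing: dF/F, median filter, z-score
#'
#' @inheritParams computeDff
#' @inheritParams denoiseZscore
#' @return a preprocessed [RoiTraces-class].
#' @export
preprocessTraces <- function(raw, baselineWindowS = 900, medianKernelFrames = 3) {
  denoiseZscore(computeDff(raw, baselineWindowS), medianKernelFrames)
}
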