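#' @include AllClasses.R utils-circular.R synthio.R
NULL

#' Integrate estimated heading from swim events
#'
#' The instantaneous angular velocity of the head-restrained fish is taken
#' as the laterality index of each swim; the heading is its cumulative sum,
#' stepping at each onset and constant between swims.
#'
#' @param events swim-event data.frame (onset_s, laterality).
#' @param rate output sampling rate, Hz.
#' @param durationS trace length, seconds.
#' @return a [HeadingTrace-class].
#' @export
integrateHeading <- function(events, rate, durationS) {
  n <- round(durationS * rate)
  steps <- numeric(n)
  if (nrow(events) > 0) {
    idx <- pmin(n, ceiling(events$onset_s * rate) + 1)
    for (i in seq_along(idx)) steps[idx[i]] <- steps[idx[i]] + events$laterality[i]
  }
  methods::new("HeadingTrace", heading = cumsum(steps), rate = rate)
}

# zero-order-hold resampling of a heading trace onto nFrames at rate
.resampleZoh <- function(values, fromRate, toRate, nOut) {
  t <- (seq_len(nOut) - 1) / toRate
  idx <- pmin(length(values), pmax(1, floor(t * fromRate) + 1))
  values[idx]
}

#' Phase-heading coupling with a rolling window and epoch shuffle
#'
#' Pearson correlation between the unwrapped phase and the (zero-order-hold
#' resampled) heading in rolling windows (default 300 s, step = window/10),
#' compared against a shuffle where each phase window is paired with a
#' non-overlapping heading epoch of the same length; the two correlation
#' populations are compared by a two-sided rank-sum test.
#'
#' @param phase a [PhaseTrace-class].
#' @param heading a [HeadingTrace-class].
#' @param windowS rolling window, seconds.
#' @param windowStepS window step, seconds (default windowS / 10).
#' @param condition optional condition label carried through.
#' @return list with window_correlations, shuffle_correlations, p_value,
#'   slope (regression of phase on heading), condition.
#' @export
phaseHeadingCoupling <- function(phase, heading, windowS = 300,
                                 windowStepS = windowS / 10,
                                 condition = NA_character_) {
  rate <- phase@rate
  u <- phase@unwrapped
  h <- .resampleZoh(heading@heading, heading@rate, rate, length(u))
  wlen <- round(windowS * rate)
  if (wlen > length(u)) stop("session shorter than one coupling window")
  step <- max(1, round(windowStepS * rate))
  starts <- seq(1, length(u) - wlen + 1, by = step)
  wcor <- vapply(starts, function(s) {
    suppressWarnings(stats::cor(u[s:(s + wlen - 1)], h[s:(s + wlen - 1)]))
  }, numeric(1))
  allStarts <- seq_len(length(u) - wlen + 1)
  scor <- vapply(starts, function(s) {
    allowed <- allStarts[allStarts + wlen - 1 < s | allStarts > s + wlen - 1]
    if (length(allowed) == 0) return(NA_real_)
    s2 <- allowed[sample.int(length(allowed), 1)]
    suppressWarnings(stats::cor(u[s:(s + wlen - 1)], h[s2:(s2 + wlen - 1)]))
  }, numeric(1))
  wcor <- wcor[is.finite(wcor)]
  scor <- scor[is.finite(scor)]
  p <- if (length(wcor) && length(scor)) {
    suppressWarnings(stats::wilcox.test(wcor, scor)$p.value)
  } else NA_real_
  slope <- unname(stats::coef(stats::lm(u ~ h))[2])
  list(window_correlations = wcor, shuffle_correlations = scor,
       p_value = p, slope = slope, condition = condition)
}

#' Event-triggered average of the network phase
#'
#' Crops the unwrapped phase around each event, subtracts the mean of the
#' 10 s pre-event baseline, and averages per event class; classes with fewer
#' than `minEvents` usable crops are omitted with a warning.
#'
#' @param phase a [PhaseTrace-class].
#' @param events data.frame with onset_s and swim_class (or a numeric vector
#'   of event times, treated as one class "event").
#' @param preS,postS window around the event, seconds.
#' @param minEvents minimum crops per class.
#' @return named list per class: `lags` (s), `mean`, `n_events`.
#' @export
triggeredAverage <- function(phase, events, preS = 10, postS = 25,
                             minEvents = 3) {
  if (is.numeric(events)) {
    events <- data.frame(onset_s = events, swim_class = "event")
  }
  rate <- phase@rate
  u <- phase@unwrapped
  nPre <- round(preS * rate)
  nPost <- round(postS * rate)
  lags <- (seq(-nPre, nPost)) / rate
  out <- list()
  for (cls in unique(events$swim_class)) {
    on <- events$onset_s[events$swim_class == cls]
    idx <- ceiling(on * rate) + 1
    idx <- idx[idx - nPre >= 1 & idx + nPost <= length(u)]
    if (length(idx) < minEvents) {
      warning(sprintf("class '%s' has fewer than %d usable events: omitted",
                      cls, minEvents))
      next
    }
    crops <- vapply(idx, function(i) {
      seg <- u[(i - nPre):(i + nPost)]
      seg - mean(seg[seq_len(nPre)])
    }, numeric(nPre + nPost + 1))
    out[[cls]] <- list(lags = lags, mean = rowMeans(crops),
                       n_events = length(idx))
  }
  out
}

#' Phase occupancy at swim onsets
#'
#' Distribution of the wrapped network phase at event onsets per swim class:
#' Rayleigh uniformity statistic per class and a Watson-Wheeler comparison
#' across classes.
#'
#' @param phase a [PhaseTrace-class].
#' @param events data.frame with onset_s and swim_class.
#' @return list with per-class `phases` and `rayleigh`, plus `crossClass`.
#' @export
phaseOccupancyAtSwims <- function(phase, events) {
  rate <- phase@rate
  idx <- pmin(length(phase@wrapped), round(events$onset_s * rate) + 1)
  ph <- phase@wrapped[idx]
  cls <- events$swim_class
  perClass <- lapply(split(ph, cls), function(a) {
    list(phases = a,
         rayleigh = if (length(a) >= 2) rayleighTest(a) else NULL)
  })
  cross <- if (length(unique(cls)) >= 2) watsonWheelerTest(ph, cls) else NULL
  list(perClass = perClass, crossClass = cross)
}

#' Regression of post-swim phase change on heading change
#'
#' For every swim, the phase change and heading change between the event
#' onset and a post-event window (default 15-20 s: mean over the window
#' minus the value just before onset) give one point; an ordinary
#' least-squares regression of delta-phase on delta-heading summarizes the
#' per-swim coupling. Events whose window exceeds the recording are dropped.
#'
#' @param phase a [PhaseTrace-class].
#' @param heading a [HeadingTrace-class].
#' @param events swim-event data.frame.
#' @param window post-event window, seconds (length 2).
#' @param minEvents minimum usable events.
#' @param condition optional label carried through.
#' @return list with slope, intercept, points (data.frame), condition.
#' @export
windowDeltaRegression <- function(phase, heading, events, window = c(15, 20),
                                  minEvents = 5, condition = NA_character_) {
  rate <- phase@rate
  u <- phase@unwrapped
  h <- .resampleZoh(heading@heading, heading@rate, rate, length(u))
  i0 <- ceiling(events$onset_s * rate) + 1
  w0 <- i0 + round(window[1] * rate)
  w1 <- i0 + round(window[2] * rate)
  ok <- w1 <= length(u) & i0 >= 2
  if (sum(ok) < minEvents) stop(sprintf("fewer than %d usable events", minEvents))
  dphi <- vapply(which(ok), function(k) {
    mean(u[w0[k]:w1[k]]) - u[i0[k] - 1]
  }, numeric(1))
  dhead <- vapply(which(ok), function(k) {
    mean(h[w0[k]:w1[k]]) - h[i0[k] - 1]
  }, numeric(1))
  if (stats::var(dhead) < 1e-14) stop("degenerate regressor: heading changes are all equal")
  fit <- stats::lm(dphi ~ dhead)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       points = data.frame(dphase = dphi, dheading = dhead),
       condition = condition)
}

#' Compare coupling slopes across conditions
#'
#' Wilcoxon signed-rank test for paired condition vectors, Mann-Whitney U
#' for unpaired, with exact small-sample p-values where available. All-zero
#' paired differences give p = 1 by convention (flagged).
#'
#' @param x,y per-session slope vectors for the two conditions.
#' @param paired logical.
#' @return list with statistic, p.value, method, allEqual flag.
#' @export
compareConditions <- function(x, y, paired = TRUE) {
  if (paired && length(x) != length(y)) stop("paired comparison needs equal lengths")
  if (paired && length(x) < 5) warning("fewer than 5 pairs: low power")
  allEqual <- paired && all(x == y)
  if (allEqual) {
    return(list(statistic = NA_real_, p.value = 1,
                method = "Wilcoxon signed rank (degenerate: all differences zero)",
                allEqual = TRUE))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = ht$method, allEqual = FALSE)
}

#' Build exponential-decay motor and gaze regressors
#'
#' Indicator arrays (1 at left or right swim onsets), the swim angular
#' velocity (laterality at onsets) and, when available, gaze direction and
#' gaze velocity are each convolved with a causal kernel exp(-t/tau)
#' (tau = 3 s) on the imaging time base.
#'
#' @param events swim-event data.frame with onset_s, laterality, swim_class.
#' @param rate time base, Hz.
#' @param durationS trace length, seconds.
#' @param gaze optional [GazeTrace-class].
#' @param tauS kernel time constant, seconds.
#' @param correlationThreshold classification threshold stored with the set.
#' @return list of class regressors: `tau_s`, `threshold`, `regressors`
#'   (named list of numeric series: left, right, ang_velocity, and gaze,
#'   gaze_velocity when a gaze trace is supplied).
#' @export
buildRegressors <- function(events, rate, durationS, gaze = NULL, tauS = 3,
                            correlationThreshold = 0.7) {
  n <- round(durationS * rate)
  ind <- function(values, onsets) {
    x <- numeric(n)
    idx <- pmin(n, ceiling(onsets * rate) + 1)
    for (i in seq_along(idx)) x[idx[i]] <- x[idx[i]] + values[i]
    x
  }
  reg <- list(
    left = expKernelFilter(ind(rep(1, sum(events$swim_class == "left")),
                               events$onset_s[events$swim_class == "left"]),
                           rate, tauS, normalize = "peak"),
    right = expKernelFilter(ind(rep(1, sum(events$swim_class == "right")),
                                events$onset_s[events$swim_class == "right"]),
                            rate, tauS, normalize = "peak"),
    ang_velocity = expKernelFilter(ind(events$laterality, events$onset_s),
                                   rate, tauS, normalize = "peak"))
  if (!is.null(gaze)) {
    g <- .resampleZoh(gaze@angle, gaze@rate, rate, n)
    reg$gaze <- expKernelFilter(g, rate, tauS, normalize = "peak")
    reg$gaze_velocity <- expKernelFilter(c(0, diff(g)) * rate, rate, tauS,
                                         normalize = "peak")
  }
  list(tau_s = tauS, threshold = correlationThreshold, regressors = reg,
       rate = rate)
}

#' Classify motor-locked ROIs by dual regressor thresholds
#'
#' An ROI is labelled "left" when its correlation with the left-swim
#' regressor exceeds the threshold while the right-swim correlation stays
#' below it (and vice versa); everything else is "none".
#'
#' @param traces a [RoiTraces-class] on the regressor time base.
#' @param regressors from [buildRegressors()].
#' @param threshold correlation threshold (default the set's 0.7).
#' @return named character vector per ROI in {left, right, none}.
#' @export
classifyMotorRois <- function(traces, regressors, threshold = regressors$threshold) {
  f <- traceValues(traces)
  cl <- suppressWarnings(stats::cor(t(f), regressors$regressors$left))
  cr <- suppressWarnings(stats::cor(t(f), regressors$regressors$right))
  out <- rep("none", nrow(f))
  out[!is.na(cl) & !is.na(cr) & cl > threshold & cr < threshold] <- "left"
  out[!is.na(cl) & !is.na(cr) & cr > threshold & cl < threshold] <- "right"
  stats::setNames(out, rownames(f))
}

#' Cross-validated regression of the phase derivative on regressors
#'
#' For each model (a named list of regressor subsets), repeatedly fits a
#' linear regression of the smoothed phase derivative on the regressors in
#' a random 5-min training epoch and scores the Pearson correlation between
#' prediction and data in a disjoint 5-min test epoch.
#'
#' @param phase a [PhaseTrace-class].
#' @param regressors from [buildRegressors()] on the phase time base.
#' @param models named list of regressor-name vectors; default gaze-only,
#'   motor-only and both (requires gaze regressors).
#' @param nDraws repetitions.
#' @param epochS epoch length, seconds.
#' @return matrix nDraws x models of test correlations.
#' @export
crossvalPhaseRegression <- function(phase, regressors,
                                    models = list(
                                      gaze = "gaze_velocity",
                                      motor = "ang_velocity",
                                      both = c("gaze_velocity", "ang_velocity")),
                                    nDraws = 500, epochS = 300) {
  rate <- phase@rate
  u <- stats::runmed(phase@unwrapped, 3)
  n <- length(u)
  dphi <- c(0, (u[3:n] - u[1:(n - 2)]) * rate / 2, 0)
  wlen <- round(epochS * rate)
  if (n < 2 * wlen) stop("recording too short to place two disjoint epochs")
  X <- do.call(cbind, regressors$regressors)
  missing <- setdiff(unlist(models), colnames(X))
  if (length(missing)) stop("unknown regressors: ", paste(missing, collapse = ", "))
  out <- matrix(NA_real_, nDraws, length(models),
                dimnames = list(NULL, names(models)))
  for (d in seq_len(nDraws)) {
    repeat {
      s1 <- sample.int(n - wlen + 1, 1)
      s2 <- sample.int(n - wlen + 1, 1)
      if (s2 + wlen - 1 < s1 || s2 > s1 + wlen - 1) break
    }
    tr <- s1:(s1 + wlen - 1)
    te <- s2:(s2 + wlen - 1)
    for (m in names(models)) {
      Xm <- X[, models[[m]], drop = FALSE]
      fit <- stats::lm.fit(cbind(1, Xm[tr, , drop = FALSE]), dphi[tr])
      pred <- cbind(1, Xm[te, , drop = FALSE]) %*% fit$coefficients
      out[d, m] <- suppressWarnings(stats::cor(pred, dphi[te]))
    }
  }
  out
}
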