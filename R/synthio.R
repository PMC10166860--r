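#' @include AllClasses.R utils-circular.R
NULL

# Causal single-exponential filter. normalize = "steady" keeps the steady
# state of a constant input (calcium kernel); "peak" keeps a unit impulse at
# height 1 (regressor kernel).
expKernelFilter <- function(x, rate, tauS, normalize = c("steady", "peak")) {
  normalize <- match.arg(normalize)
  if (tauS <= 0) return(x)
  a <- exp(-1 / (rate * tauS))
  gain <- if (normalize == "steady") 1 - a else 1
  as.numeric(stats::filter(gain * x, a, method = "recursive",
                           init = if (normalize == "steady") x[1] else 0))
}

.runWithSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a Poisson swim-bout sequence
#'
#' Bout onsets follow a Poisson process of rate `swimRateHz`, thinned by a
#' short refractory period so bouts never overlap. Each bout's laterality
#' index is drawn from the symmetric trimodal mixture
#' w_c N(0, sd_c) + w_s N(+mu, sd_s) + w_s N(-mu, sd_s) and its class is
#' recorded from the generating component (positive laterality = rightward).
#'
#' @param params a [SessionParams-class] object.
#' @return data.frame with onset_s, offset_s, laterality, swim_class.
#' @export
simulateSwimSequence <- function(params) {
  empty <- data.frame(onset_s = numeric(), offset_s = numeric(),
                      laterality = numeric(), swim_class = character(),
                      stringsAsFactors = FALSE)
  if (params@swimRateHz <= 0) return(empty)
  # oversample exponential gaps, then thin
  nMax <- max(10, ceiling(params@durationS * params@swimRateHz * 3 + 20))
  gaps <- stats::rexp(nMax, rate = params@swimRateHz)
  onsets <- cumsum(gaps)
  durations <- stats::runif(nMax, params@boutDurationRangeS[1],
                            params@boutDurationRangeS[2])
  keep <- logical(nMax)
  lastOffset <- -Inf
  maxOnset <- params@durationS - params@boutDurationRangeS[2] - 0.1
  for (i in seq_len(nMax)) {
    if (onsets[i] > maxOnset) break
    if (onsets[i] >= lastOffset + params@boutRefractoryS) {
      keep[i] <- TRUE
      lastOffset <- onsets[i] + durations[i]
    }
  }
  n <- sum(keep)
  if (n == 0) return(empty)
  wC <- params@lateralityCentralWeight
  comp <- sample(c("forward", "right", "left"), n, replace = TRUE,
                 prob = c(wC, (1 - wC) / 2, (1 - wC) / 2))
  lat <- numeric(n)
  lat[comp == "forward"] <- stats::rnorm(sum(comp == "forward"), 0,
                                         params@lateralityCentralSd)
  lat[comp == "right"] <- stats::rnorm(sum(comp == "right"),
                                       params@lateralitySideMean,
                                       params@lateralitySideSd)
  lat[comp == "left"] <- stats::rnorm(sum(comp == "left"),
                                      -params@lateralitySideMean,
                                      params@lateralitySideSd)
  data.frame(onset_s = onsets[keep], offset_s = onsets[keep] + durations[keep],
             laterality = lat, swim_class = comp, stringsAsFactors = FALSE)
}

#' Render a tail-angle trace from swim events
#'
#' Each bout is a decaying sinusoidal oscillation (default 25 Hz carrier,
#' 100 ms envelope) plus a constant bias chosen so that the mean tail angle
#' over the bout's first 70 ms equals the event's laterality index exactly,
#' making the trace invertible by [detectSwims()]. Between bouts the trace is
#' zero plus optional low-amplitude noise.
#'
#' @param events swim-event data.frame (onset_s, offset_s, laterality).
#' @param params a [SessionParams-class] object.
#' @return a [TailTrace-class] at `behaviorRateHz`.
#' @export
synthesizeTailTrace <- function(events, params) {
  rate <- params@behaviorRateHz
  n <- round(params@durationS * rate)
  angle <- if (params@tailNoiseSd > 0)
    stats::rnorm(n, 0, params@tailNoiseSd) else numeric(n)
  if (nrow(events) > 0) {
    events <- events[order(events$onset_s), , drop = FALSE]
    merged <- FALSE
    lastEnd <- -Inf
    for (i in seq_len(nrow(events))) {
      i0 <- floor(events$onset_s[i] * rate) + 1
      i1 <- min(n, floor(events$offset_s[i] * rate) + 1)
      if (i0 <= lastEnd) {
        merged <- TRUE
        i0 <- lastEnd + 1
        if (i0 > i1) next
      }
      tRel <- (seq(i0, i1) - i0) / rate
      osc <- params@boutAmplitude * exp(-tRel / 0.1) *
        sin(2 * pi * params@boutCarrierHz * tRel)
      first70 <- tRel < 0.07
      bias <- events$laterality[i] - mean(osc[first70])
      angle[i0:i1] <- bias + osc
      lastEnd <- i1
    }
    if (merged) warning("overlapping bouts were merged")
  }
  TailTrace(angle = angle, rate = rate)
}

#' Place ring and distractor ROIs in the anatomical frame
#'
#' Ring ROIs are laid on an ellipse in the horizontal plane so that the
#' anatomical angle atan2(lr, -rc) matches the ROI's ground-truth ring angle
#' (caudal = 0, left = +pi/2, right = -pi/2, clockwise-increasing viewed from
#' above); distractor ROIs are scattered outside the ellipse.
#'
#' @param params a [SessionParams-class] object.
#' @return data.frame with roi_id, lr, rc, dv, is_ring, true_alpha.
#' @export
placeRingRois <- function(params) {
  nRing <- params@nNeurons
  alpha <- wrapToPi(-pi + 2 * pi * seq_len(nRing) / nRing)
  a <- params@ringRadiusUm * params@ringEllipseRatio   # left-right semiaxis
  b <- params@ringRadiusUm                             # rostro-caudal semiaxis
  jit <- params@positionJitterUm
  lr <- a * sin(alpha) + stats::rnorm(nRing, 0, jit)
  rc <- -b * cos(alpha) + stats::rnorm(nRing, 0, jit)
  dv <- stats::rnorm(nRing, 0, jit)
  nDis <- round(nRing * params@distractorFraction /
                  (1 - params@distractorFraction))
  if (nDis > 0) {
    th <- stats::runif(nDis, -pi, pi)
    rad <- params@ringRadiusUm * stats::runif(nDis, 1.6, 2.6)
    lr <- c(lr, rad * sin(th))
    rc <- c(rc, -rad * cos(th))
    dv <- c(dv, stats::rnorm(nDis, 0, 4 * jit))
  }
  nTot <- nRing + nDis
  data.frame(roi_id = sprintf("R%03d", seq_len(nTot)), lr = lr, rc = rc,
             dv = dv, is_ring = rep(c(TRUE, FALSE), c(nRing, nDis)),
             true_alpha = c(alpha, rep(NA_real_, nDis)),
             stringsAsFactors = FALSE)
}

# tuning function g(theta), peak 1 at theta = 0
.tuningFun <- function(theta, shape, kappa) {
  switch(shape,
         raised_cosine = 0.5 * (1 + cos(theta)),
         von_mises = exp(kappa * (cos(theta) - 1)))
}

#' Render calcium activity traces from ground truth
#'
#' Ring ROI i is driven by amplitude * g(truePhase(t) - alpha_i) with g the
#' configured tuning curve; the drive is passed through a causal
#' single-exponential indicator kernel (decay `calciumTauS`, steady-state
#' normalized) and i.i.d. Gaussian noise is added. Distractor ROIs carry
#' noise, and a configurable fraction additionally carries a motor-locked
#' signal (the left or right swim indicator through the same kernel).
#'
#' @param truth a [GroundTruth-class] object.
#' @param roi ROI table from [placeRingRois()].
#' @param params a [SessionParams-class] object.
#' @return a [RoiTraces-class] of activity (signal units, not raw F).
#' @export
renderCalcium <- function(truth, roi, params) {
  nFrames <- length(truth@truePhase)
  rate <- params@imagingRateHz
  ring <- which(roi$is_ring)
  dis <- which(!roi$is_ring)
  values <- matrix(0, nrow(roi), nFrames)
  drive <- params@amplitude *
    .tuningFun(outer(roi$true_alpha[ring], truth@truePhase, function(a, p) p - a),
               params@tuningShape, params@tuningKappa)
  for (k in seq_along(ring)) {
    values[ring[k], ] <- expKernelFilter(drive[k, ], rate, params@calciumTauS)
  }
  if (length(dis) > 0 && params@motorLockedFraction > 0) {
    nMotor <- round(length(dis) * params@motorLockedFraction)
    if (nMotor > 0) {
      ev <- truth@swimEvents
      for (side in c("left", "right")) {
        ind <- numeric(nFrames)
        onsets <- ev$onset_s[ev$swim_class == side]
        idx <- pmin(nFrames, ceiling(onsets * rate) + 1)
        ind[idx] <- 1
        sig <- expKernelFilter(ind, rate, params@calciumTauS,
                               normalize = "peak")
        who <- dis[seq_len(nMotor)]
        who <- who[seq_along(who) %% 2 == (side == "left")]
        for (j in who) values[j, ] <- params@amplitude * sig
      }
    }
  }
  if (params@noiseSd > 0) {
    values <- values + matrix(stats::rnorm(length(values), 0, params@noiseSd),
                              nrow(values))
  }
  RoiTraces(values, rate = rate, roi = roi, roiIds = roi$roi_id,
            preprocessed = FALSE)
}

# piecewise-constant unwrapped phase: step -phaseGain * laterality at onsets
.integrateTruePhase <- function(events, params) {
  nFrames <- round(params@durationS * params@imagingRateHz)
  phase <- numeric(nFrames)
  if (nrow(events) > 0) {
    idx <- pmin(nFrames, ceiling(events$onset_s * params@imagingRateHz) + 1)
    steps <- numeric(nFrames)
    for (i in seq_along(idx)) {
      steps[idx[i]] <- steps[idx[i]] - params@phaseGain * events$laterality[i]
    }
    phase <- cumsum(steps)
  }
  phase
}

.integrateTrueHeading <- function(events, params) {
  nFrames <- round(params@durationS * params@behaviorRateHz)
  heading <- numeric(nFrames)
  if (nrow(events) > 0) {
    idx <- pmin(nFrames, ceiling(events$onset_s * params@behaviorRateHz) + 1)
    steps <- numeric(nFrames)
    for (i in seq_along(idx)) steps[idx[i]] <- steps[idx[i]] + events$laterality[i]
    heading <- cumsum(steps)
  }
  heading
}

.simulateGaze <- function(params) {
  if (params@gazeSaccadeRateHz <= 0) return(NULL)
  rate <- params@behaviorRateHz
  n <- round(params@durationS * rate)
  nSac <- stats::rpois(1, params@gazeSaccadeRateHz * params@durationS)
  times <- sort(stats::runif(nSac, 1, params@durationS - 1))
  angle <- numeric(n)
  cur <- 0
  if (nSac > 0) {
    idx <- floor(times * rate) + 1
    steps <- numeric(n)
    steps[idx] <- stats::rnorm(nSac, 0, params@gazeSaccadeSd)
    angle <- cumsum(steps)
  }
  GazeTrace(angle = angle, rate = rate, saccadeTimes = times)
}

#' Simulate a complete synthetic ring-attractor session
#'
#' Deterministic given `params@seed`: a swim sequence drives both the tail
#' trace and the network phase (left swims rotate the bump clockwise,
#' increasing phase, while the integrated heading decreases), ring ROIs with
#' sinusoidal tuning render calcium signals, and raw fluorescence is produced
#' as baselineF * (1 + signal) with a slow linear bleaching trend so the
#' preprocessing stage is exercised end to end.
#'
#' @param params a [SessionParams-class] object.
#' @return a [SyntheticSession-class] object.
#' @export
simulateSession <- function(params = sessionParams()) {
  .runWithSeed(params@seed, {
    events <- simulateSwimSequence(params)
    tail <- synthesizeTailTrace(events, params)
    roi <- placeRingRois(params)
    truth <- methods::new("GroundTruth",
                          truePhase = .integrateTruePhase(events, params),
                          trueHeading = .integrateTrueHeading(events, params),
                          trueAlpha = roi$true_alpha[roi$is_ring],
                          swimEvents = events)
    signal <- renderCalcium(truth, roi, params)
    gaze <- .simulateGaze(params)
    nFrames <- ncol(signal)
    bleach <- 1 - params@bleachFraction * seq(0, 1, length.out = nFrames)
    raw <- params@baselineF * (1 + traceValues(signal)) *
      matrix(bleach, nrow(signal), nFrames, byrow = TRUE)
    traces <- RoiTraces(raw, rate = params@imagingRateHz, roi = roi,
                        roiIds = roi$roi_id, preprocessed = FALSE)
    methods::new("SyntheticSession", traces = traces, signal = signal,
                 tail = tail, gaze = gaze, truth = truth, params = params)
  })
}

#' Ground-truth circular embedding of a synthetic session
#'
#' The ring ROIs placed at their true angles on the unit circle; decoding
#' against it isolates the population-vector decoder from embedding
#' estimation.
#'
#' @param session a [SyntheticSession-class].
#' @return an [RpcEmbedding-class] over the ring ROIs.
#' @export
trueEmbedding <- function(session) {
  roi <- roiInfo(session@traces)
  ids <- roi$roi_id[roi$is_ring]
  a <- session@truth@trueAlpha
  methods::new("RpcEmbedding", coords = cbind(cos(a), sin(a)),
               alpha = as.numeric(a),
               transform = list(center = c(0, 0), radius = 1, rotation = 0,
                                reflection = FALSE),
               anchorAngles = c(0, 0), roiIds = ids)
}

#' @rdname sessionTruth
#' @export
sessionSignal <- function(x) x@signal
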