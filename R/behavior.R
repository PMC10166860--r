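#' @include AllClasses.R
NULL

#' Reference swim-classification threshold
#'
#' Fallback laterality threshold (radians) for left/forward/right
#' classification when no trimodal fit is available; the intersection of the
#' central and lateral mixture components at the reference operating point.
#' @export
DEFAULT_SWIM_THRESHOLD <- 0.239

#' Swim vigor: rolling standard deviation of the tail angle
#'
#' Right-aligned rolling s.d. in a 50 ms window, zero-padded at the start so
#' the output has the same length as the input.
#'
#' @param tail a [TailTrace-class].
#' @param windowMs window length in milliseconds (>= 2 samples).
#' @return numeric vigor series, radians.
#' @export
computeVigor <- function(tail, windowMs = 50) {
  x <- tail@angle
  n <- length(x)
  w <- round(windowMs / 1000 * tail@rate)
  if (w < 2) stop("vigor window must span at least 2 samples")
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  v <- numeric(n)
  t <- seq(w, n)
  s1 <- cs[t + 1] - cs[t + 1 - w]
  s2 <- cs2[t + 1] - cs2[t + 1 - w]
  v[t] <- sqrt(pmax(0, (s2 - s1^2 / w) / (w - 1)))
  v
}

#' Detect swim bouts from a tail trace
#'
#' Swims are maximal episodes where the vigor exceeds `threshold`; episodes
#' closer than `minGapMs` are merged. The laterality index of each swim is
#' the mean tail angle over its first 70 ms.
#'
#' @param tail a [TailTrace-class].
#' @param threshold vigor threshold (0.1 for all fish).
#' @param minGapMs merge gap, milliseconds.
#' @param vigorWindowMs window for [computeVigor()].
#' @return data.frame with onset_s, offset_s, laterality, swim_class (NA).
#' @export
detectSwims <- function(tail, threshold = 0.1, minGapMs = 100,
                        vigorWindowMs = 50) {
  v <- computeVigor(tail, vigorWindowMs) > threshold
  rate <- tail@rate
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  if (length(on) == 0) {
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      laterality = numeric(), swim_class = character(),
                      stringsAsFactors = FALSE))
  }
  s <- starts[on]
  e <- ends[on]
  gap <- round(minGapMs / 1000 * rate)
  keep <- rep(TRUE, length(s))
  for (i in seq_along(s)[-1]) {
    j <- max(which(keep[seq_len(i - 1)]))
    if (s[i] - e[j] <= gap) {
      e[j] <- e[i]
      keep[i] <- FALSE
    }
  }
  s <- s[keep]
  e <- e[keep]
  w70 <- round(0.07 * rate)
  lat <- vapply(seq_along(s), function(i) {
    mean(tail@angle[s[i]:min(length(tail@angle), s[i] + w70 - 1)])
  }, numeric(1))
  data.frame(onset_s = (s - 1) / rate, offset_s = (e - 1) / rate,
             laterality = lat, swim_class = NA_character_,
             stringsAsFactors = FALSE)
}

# trimodal mixture density with symmetric side components
.trimodalDensity <- function(x, wC, sdC, mu, sdS) {
  wS <- (1 - wC) / 2
  wC * stats::dnorm(x, 0, sdC) + wS * stats::dnorm(x, mu, sdS) +
    wS * stats::dnorm(x, -mu, sdS)
}

# positive abscissa where central and side component densities intersect
.trimodalIntersection <- function(wC, sdC, mu, sdS) {
  wS <- (1 - wC) / 2
  f <- function(x) wC * stats::dnorm(x, 0, sdC) - wS * stats::dnorm(x, mu, sdS)
  lo <- 1e-6
  hi <- mu - 1e-6
  if (hi <= lo || f(lo) <= 0 || f(hi) >= 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Fit a symmetric trimodal Gaussian mixture to laterality indices
#'
#' Least-squares fit of w_c N(0, sd_c) + w_s N(+mu, sd_s) + w_s N(-mu, sd_s)
#' (side components mirror-symmetric, w_c + 2 w_s = 1) to the binned density
#' of swim laterality indices. The classification threshold is the positive
#' abscissa in (0, mu) where the central and side component densities
#' intersect.
#'
#' @param lateralities laterality indices, radians.
#' @param nBins histogram bin count (symmetric range).
#' @return list with central_sd, side_mean, side_sd, weights (central, side,
#'   side), threshold and the fitted density function.
#' @export
fitTrimodal <- function(lateralities, nBins = 61) {
  lateralities <- lateralities[is.finite(lateralities)]
  if (length(lateralities) < 30) {
    warning("fewer than 30 swims: trimodal fit may be unreliable")
  }
  r <- max(abs(lateralities))
  breaks <- seq(-r - 1e-9, r + 1e-9, length.out = nBins + 1)
  h <- graphics::hist(lateralities, breaks = breaks, plot = FALSE)
  centers <- h$mids
  dens <- h$density
  # moment-based initialization
  absl <- abs(lateralities)
  mu0 <- stats::median(absl[absl > stats::quantile(absl, 0.5)])
  sdC0 <- stats::sd(lateralities[absl < mu0 / 2])
  if (!is.finite(sdC0) || sdC0 <= 0) sdC0 <- mu0 / 5
  sdS0 <- sdC0 * 1.5
  wC0 <- mean(absl < mu0 / 2)
  obj <- function(p) {
    wC <- stats::plogis(p[1])
    sdC <- exp(p[2])
    mu <- exp(p[3])
    sdS <- exp(p[4])
    sum((dens - .trimodalDensity(centers, wC, sdC, mu, sdS))^2)
  }
  fit <- stats::optim(c(stats::qlogis(min(max(wC0, 0.05), 0.95)), log(sdC0),
                        log(mu0), log(sdS0)),
                      obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  if (fit$convergence != 0) {
    stop("trimodal fit did not converge; consider the fixed fallback threshold ",
         "DEFAULT_SWIM_THRESHOLD")
  }
  wC <- stats::plogis(fit$par[1])
  sdC <- exp(fit$par[2])
  mu <- exp(fit$par[3])
  sdS <- exp(fit$par[4])
  thr <- .trimodalIntersection(wC, sdC, mu, sdS)
  if (!is.finite(thr)) {
    stop("central and side components do not intersect in (0, side_mean); ",
         "consider the fixed fallback threshold DEFAULT_SWIM_THRESHOLD")
  }
  list(central_sd = sdC, side_mean = mu, side_sd = sdS,
       weights = c(central = wC, side = (1 - wC) / 2, side = (1 - wC) / 2),
       threshold = thr,
       density = function(x) .trimodalDensity(x, wC, sdC, mu, sdS),
       sse = fit$value)
}

#' Classify swims as left, forward or right
#'
#' Laterality above +threshold is a rightward swim, below -threshold a
#' leftward swim, otherwise forward (positive laterality = rightward by the
#' package convention).
#'
#' @param events swim-event data.frame from [detectSwims()].
#' @param fit trimodal fit from [fitTrimodal()], or a plain numeric threshold.
#' @return `events` with swim_class filled in.
#' @export
classifySwims <- function(events, fit = DEFAULT_SWIM_THRESHOLD) {
  thr <- if (is.numeric(fit)) fit else fit$threshold
  cls <- rep("forward", nrow(events))
  cls[events$laterality > thr] <- "right"
  cls[events$laterality < -thr] <- "left"
  events$swim_class <- cls
  events
}

#' Gaze direction and saccade detection from the two eye angles
#'
#' Gaze is the average of the left and right eye angles; saccades are times
#' where the absolute gaze velocity exceeds `saccadeVelocityThreshold`,
#' merged within 100 ms.
#'
#' @param leftEye,rightEye eye-angle series, radians, equal length.
#' @param rate sampling rate, Hz.
#' @param saccadeVelocityThreshold rad/s.
#' @return a [GazeTrace-class].
#' @export
computeGaze <- function(leftEye, rightEye, rate, saccadeVelocityThreshold = 2) {
  if (length(leftEye) != length(rightEye)) {
    stop("left and right eye traces must have the same length")
  }
  gaze <- (leftEye + rightEye) / 2
  vel <- c(0, diff(gaze)) * rate
  fast <- which(abs(vel) > saccadeVelocityThreshold)
  times <- numeric()
  if (length(fast) > 0) {
    gapped <- c(TRUE, diff(fast) > round(0.1 * rate))
    times <- (fast[gapped] - 1) / rate
  }
  GazeTrace(angle = gaze, rate = rate, saccadeTimes = times)
}
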