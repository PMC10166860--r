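phaseOf <- function(u, rate = 5) {
  methods::new("PhaseTrace", wrapped = wrapToPi(u), unwrapped = u,
               vectorNorm = rep(1, length(u)), rate = rate)
}

test_that("heading integration is exact, linear and order-independent", {
  none <- integrateHeading(data.frame(onset_s = numeric(),
                                      laterality = numeric()), 10, 30)
  expect_identical(unique(headingValues(none)), 0)
  ev <- data.frame(onset_s = c(5, 15), laterality = c(0.5, -0.5))
  h <- integrateHeading(ev, 10, 30)
  expect_equal(headingValues(h)[300], 0, tolerance = 1e-12)
  expect_equal(max(headingValues(h)), 0.5, tolerance = 1e-12)
  k <- 7; L <- 0.3
  evK <- data.frame(onset_s = seq(1, 25, length.out = k), laterality = rep(L, k))
  expect_equal(headingValues(integrateHeading(evK, 10, 30))[300], k * L,
               tolerance = 1e-12)
  evP <- evK[sample(k), ]
  expect_equal(headingValues(integrateHeading(evP, 10, 30))[300], k * L,
               tolerance = 1e-12)
})

test_that("coupling: exact antiphase gives window correlations of -1", {
  set.seed(51)
  u <- cumsum(rnorm(1800, 0, 0.1))   # 30 min at 1 Hz
  ph <- phaseOf(u, rate = 1)
  h <- methods::new("HeadingTrace", heading = -u, rate = 1)
  cp <- phaseHeadingCoupling(ph, h)
  expect_true(all(abs(cp$window_correlations + 1) < 1e-9))
  expect_lt(cp$p_value, 0.01)
  expect_equal(cp$slope, -1, tolerance = 1e-9)
  expect_error(phaseHeadingCoupling(phaseOf(u[1:100], rate = 1), h), "shorter")
})

test_that("coupling test is calibrated on independent random walks", {
  set.seed(52)
  pvals <- replicate(100, {
    u <- cumsum(rnorm(1800, 0, 0.2))   # 1 Hz, 30 min
    h <- methods::new("HeadingTrace",
                      heading = cumsum(rnorm(1800, 0, 0.2)), rate = 1)
    phaseHeadingCoupling(phaseOf(u, rate = 1), h, windowStepS = 300)$p_value
  })
  expect_gte(mean(pvals > 0.05), 0.90)
})

test_that("triggered averages plateau at the programmed step size", {
  rate <- 5
  n <- 3000
  on <- seq(50, 550, by = 50)
  u <- numeric(n)
  idx <- ceiling(on * rate) + 1
  step <- numeric(n); step[idx] <- 0.8
  u <- cumsum(step)
  ev <- data.frame(onset_s = on, swim_class = "left")
  ta <- triggeredAverage(phaseOf(u), ev)
  expect_identical(ta$left$n_events, length(on))
  expect_equal(ta$left$mean[ta$left$lags > 1], rep(0.8, sum(ta$left$lags > 1)),
               tolerance = 1e-9)
  expect_equal(max(abs(ta$left$mean[ta$left$lags < 0])), 0, tolerance = 1e-9)
  # constant phase gives a zero curve; small classes are omitted
  ta0 <- triggeredAverage(phaseOf(rep(1, n)), ev)
  expect_identical(max(abs(ta0$left$mean)), 0)
  evSmall <- data.frame(onset_s = c(100, 200), swim_class = "right")
  expect_warning(taS <- triggeredAverage(phaseOf(u), evSmall), "omitted")
  expect_identical(length(taS), 0L)
})

test_that("swim-triggered phase changes mirror left/right on synthetic data", {
  s <- refSession(1)
  ph <- decodeTrue(s)
  ev <- sessionTruth(s)@swimEvents
  ta <- suppressWarnings(triggeredAverage(ph, ev))
  lateLags <- ta$left$lags > 15
  expect_gt(mean(ta$left$mean[lateLags]), 0)    # left swims increase phase
  expect_lt(mean(ta$right$mean[lateLags]), 0)
  asym <- abs(mean(ta$left$mean[lateLags]) + mean(ta$right$mean[lateLags]))
  expect_lt(asym, 0.35 * abs(mean(ta$left$mean[lateLags])))
})

test_that("phase occupancy at swims: uniform accepted, locked rejected", {
  set.seed(53)
  nullP <- replicate(100, {
    ph <- phaseOf(runif(2000, -pi, pi))
    ev <- data.frame(onset_s = runif(40, 1, 390), swim_class = "left")
    phaseOccupancyAtSwims(ph, ev)$perClass$left$rayleigh$p.value
  })
  expect_gte(mean(nullP > 0.05), 0.85)
  phLock <- phaseOf(rnorm(2000, 0, 0.1))
  evL <- data.frame(onset_s = runif(40, 1, 390), swim_class = "left")
  expect_lt(phaseOccupancyAtSwims(phLock, evL)$perClass$left$rayleigh$p.value,
            0.01)
  # identical distributions across classes: cross-class test non-significant
  ph <- phaseOf(runif(4000, -pi, pi))
  ev2 <- data.frame(onset_s = runif(200, 1, 790),
                    swim_class = rep(c("left", "right"), 100))
  expect_gt(phaseOccupancyAtSwims(ph, ev2)$crossClass$p.value, 0.01)
})

test_that("window-delta regression recovers the programmed gain", {
  s <- memo("cleanKernelFree3",
            simulateSession(sessionParams(seed = 3, noiseSd = 0,
                                          calciumTauS = 1e-9,
                                          bleachFraction = 0)))
  ph <- decodeTrue(s)
  ev <- sessionTruth(s)@swimEvents
  h <- integrateHeading(ev, 400, 600)
  wd <- windowDeltaRegression(ph, h, ev)
  expect_equal(wd$slope, -1, tolerance = 0.02)
  # adding a constant to the phase leaves the slope unchanged
  ph2 <- phaseOf(unwrappedPhase(ph) + 3, rate = 5)
  expect_equal(windowDeltaRegression(ph2, h, ev)$slope, wd$slope,
               tolerance = 1e-9)
  # forward-swims-only heading is a degenerate regressor
  evF <- data.frame(onset_s = seq(30, 300, by = 30), laterality = 0)
  hF <- integrateHeading(evF, 400, 600)
  expect_error(windowDeltaRegression(ph, hF, evF), "degenerate")
})

test_that("condition comparison matches exact rank-based oracles", {
  expect_identical(compareConditions(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))$p.value, 1)
  # disjoint distributions, n = 8 vs 8: exact Mann-Whitney enumeration
  x <- 1:8; y <- 101:108
  got <- compareConditions(x, y, paired = FALSE)$p.value
  # oracle: P(U <= 0 or U >= 64) over all C(16, 8) rank assignments = 2/12870
  expect_equal(got, 2 / choose(16, 8), tolerance = 1e-12)
  # gain-independent slopes: no pairwise comparison significant most of the time
  set.seed(54)
  anySig <- replicate(100, {
    slopes <- matrix(rnorm(15, -1, 0.2), 5, 3)   # 5 fish x 3 gain conditions
    ps <- c(compareConditions(slopes[, 1], slopes[, 2])$p.value,
            compareConditions(slopes[, 1], slopes[, 3])$p.value,
            compareConditions(slopes[, 2], slopes[, 3])$p.value)
    any(ps < 0.05)
  })
  expect_lte(mean(anySig), 0.25)
})

test_that("regressors are exponential kernels on the event trains", {
  rate <- 5; dur <- 100
  none <- buildRegressors(data.frame(onset_s = numeric(),
                                     laterality = numeric(),
                                     swim_class = character()), rate, dur)
  expect_identical(sum(abs(none$regressors$left)), 0)
  ev <- data.frame(onset_s = 10, laterality = -0.5, swim_class = "left")
  reg <- buildRegressors(ev, rate, dur, tauS = 3)
  r <- reg$regressors$left
  i0 <- as.integer(ceiling(10 * rate) + 1)
  expect_identical(which.max(r), i0)
  expect_equal(r[i0], 1, tolerance = 1e-12)
  k <- 0:20
  expect_equal(r[i0 + k], exp(-k / (rate * 3)), tolerance = 1e-9)
  expect_equal(reg$regressors$ang_velocity, -0.5 * r, tolerance = 1e-12)
  # a trace equal to a regressor correlates 1 with it
  tr <- zTraces(matrix(r, 1), rate = rate)
  expect_equal(unname(cor(traceValues(tr)[1, ], r)), 1, tolerance = 1e-12)
})

test_that("motor ROI classification follows the dual-threshold rule", {
  s <- refSession(1)
  ev <- sessionTruth(s)@swimEvents
  reg <- buildRegressors(ev, 5, 600)
  set.seed(55)
  v <- rbind(reg$regressors$left + rnorm(3000, 0, 0.05),
             reg$regressors$left + reg$regressors$right,
             rnorm(3000))
  cls <- classifyMotorRois(zTraces(v), reg)
  expect_identical(unname(cls[1]), "left")
  expect_identical(unname(cls[3]), "none")
  bothHigh <- 0.6 * scale(reg$regressors$left) + 0.6 * scale(reg$regressors$right)
  clsB <- classifyMotorRois(zTraces(matrix(bothHigh, 1)), reg)
  if (cor(bothHigh, reg$regressors$left) > 0.7 &&
      cor(bothHigh, reg$regressors$right) > 0.7) {
    expect_identical(unname(clsB[1]), "none")
  }
  # motor-locked distractors in the synthetic session are found
  res <- refAnalysis(1)
  roi <- roiInfo(sessionTraces(s))
  allCls <- classifyMotorRois(res$traces, reg)
  motorIds <- names(allCls)[allCls != "none"]
  expect_gt(length(motorIds), 0)
  expect_true(all(!roi$is_ring[match(motorIds, roi$roi_id)]))
})

test_that("cross-validated regression separates informative models from null", {
  set.seed(56)
  rate <- 5; n <- 6000
  ev <- data.frame(onset_s = sort(runif(80, 1, n / rate - 30)),
                   laterality = rnorm(80, 0, 0.5),
                   swim_class = sample(c("left", "right"), 80, TRUE))
  reg <- buildRegressors(ev, rate, n / rate)
  u <- cumsum(reg$regressors$ang_velocity) / rate
  ph <- phaseOf(u, rate)
  cv <- crossvalPhaseRegression(ph, reg, models = list(motor = "ang_velocity"),
                                nDraws = 30)
  expect_gt(median(cv[, "motor"]), 0.8)
  phNull <- phaseOf(cumsum(rnorm(n, 0, 0.1)), rate)
  cvN <- crossvalPhaseRegression(phNull, reg,
                                 models = list(motor = "ang_velocity"),
                                 nDraws = 50)
  expect_lt(abs(median(cvN[, "motor"])), 0.25)
  expect_error(crossvalPhaseRegression(phaseOf(u[1:100], rate), reg),
               "too short")
})

test_that("combined gaze + motor model beats single-predictor models", {
  s <- memo("gazeSession600",
            simulateSession(sessionParams(seed = 13, gazeSaccadeRateHz = 0.08,
                                          durationS = 1500)))
  ev <- sessionTruth(s)@swimEvents
  gz <- sessionGaze(s)
  rate <- 5
  reg <- buildRegressors(ev, rate, 1500, gaze = gz)
  # phase driven by swims plus a gaze-locked wobble
  u <- cumsum(reg$regressors$ang_velocity) / rate +
    0.3 * reg$regressors$gaze_velocity
  cv <- crossvalPhaseRegression(phaseOf(u, rate), reg, nDraws = 40)
  expect_gte(median(cv[, "both"]), median(cv[, "motor"]) - 0.02)
  expect_gte(median(cv[, "both"]), median(cv[, "gaze"]) - 0.02)
})
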