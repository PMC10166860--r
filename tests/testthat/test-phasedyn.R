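embOf <- function(alpha, ids = sprintf("R%03d", seq_along(alpha))) {
  methods::new("RpcEmbedding", coords = cbind(cos(alpha), sin(alpha)),
               alpha = alpha,
               transform = list(center = c(0, 0), radius = 1, rotation = 0,
                                reflection = FALSE),
               anchorAngles = c(0, 0), roiIds = ids)
}

test_that("single-active-ROI frames decode to that ROI's angle", {
  alpha <- c(0, pi / 2, pi, -pi / 2)
  e <- embOf(alpha)
  f <- diag(4)   # frame t activates only ROI t
  ph <- computePhase(zTraces(f), e)
  expect_equal(wrappedPhase(ph), alpha, tolerance = 1e-9)
})

test_that("a raised-cosine bump at 2.0 rad decodes to 2.0 exactly", {
  alpha <- -pi + 2 * pi * seq_len(16) / 16
  f <- matrix(0.5 * (1 + cos(2.0 - alpha)), ncol = 1)
  ph <- computePhase(zTraces(f), embOf(alpha))
  expect_equal(wrappedPhase(ph), 2.0, tolerance = 1e-6)
})

test_that("decoding is offset-invariant and equivariant to embedding rotation", {
  set.seed(31)
  alpha <- -pi + 2 * pi * seq_len(12) / 12
  f <- matrix(rnorm(12 * 20), 12, 20)
  e <- embOf(alpha)
  p1 <- computePhase(zTraces(f), e, clipQuantiles = NULL)
  p2 <- computePhase(zTraces(f + matrix(5, 12, 20, byrow = TRUE) *
                              rep(runif(20), each = 12)), e,
                     clipQuantiles = NULL)
  expect_equal(wrappedPhase(p1), wrappedPhase(p2), tolerance = 1e-9)
  delta <- 0.7
  eRot <- embOf(wrapToPi(alpha + delta))
  p3 <- computePhase(zTraces(f), eRot, clipQuantiles = NULL)
  expect_equal(wrapToPi(wrappedPhase(p3) - wrappedPhase(p1)),
               rep(delta, 20), tolerance = 1e-9)
})

test_that("computePhase matches the direct vector-sum oracle to 1e-9", {
  set.seed(32)
  nRoi <- 30; nF <- 100
  alpha <- runif(nRoi, -pi, pi)
  f <- matrix(rnorm(nRoi * nF), nRoi, nF)
  e <- embOf(alpha)
  ph <- computePhase(zTraces(f), e)
  # independent oracle: clip, center, loop over frames summing coordinates
  fo <- f
  for (i in seq_len(nRoi)) {
    q <- quantile(fo[i, ], c(0.02, 0.98), names = FALSE)
    fo[i, ] <- pmin(pmax(fo[i, ], q[1]), q[2])
  }
  oracle <- vapply(seq_len(nF), function(t) {
    ft <- fo[, t] - mean(fo[, t])
    vx <- sum(ft * cos(alpha)) / nRoi
    vy <- sum(ft * sin(alpha)) / nRoi
    atan2(vy, vx)
  }, numeric(1))
  expect_lt(max(abs(circDist(wrappedPhase(ph), oracle))), 1e-9)
})

test_that("unwrapping removes 2*pi discontinuities and re-wrapping inverts it", {
  expect_identical(unwrapPhase(rep(0.3, 10)), rep(0.3, 10))
  ramp <- seq(0, 6 * pi, length.out = 200)
  saw <- wrapToPi(ramp)
  u <- unwrapPhase(saw)
  expect_true(all(diff(u) >= 0))
  expect_equal(u - u[1], ramp - ramp[1], tolerance = 1e-9)
  expect_equal(wrapToPi(u), saw, tolerance = 1e-12)
})

test_that("phase-zeroed profile recovers the raised-cosine bump shape", {
  s <- refCleanSession(2)
  e <- trueEmbedding(s)
  sig <- sessionSignal(s)[roiIds(e), ]
  ph <- computePhase(sig, e)
  prof <- phaseZeroedProfile(sig, e, ph)
  expect_equal(prof@fwhm, pi, tolerance = 0.1)
  analytic <- 0.5 * (1 + cos(prof@bins))
  expect_lt(max(abs(prof@mean - analytic)), 0.02)
  # interpolated and raw-sorted variants agree
  rawInterp <- approx(prof@raw$angles[order(prof@raw$angles)],
                      prof@raw$mean[order(prof@raw$angles)],
                      xout = prof@bins, rule = 2)$y
  expect_gt(cor(rawInterp, prof@mean), 0.98)
})

test_that("a phase-shuffled control flattens the bump profile", {
  s <- refCleanSession(2)
  e <- trueEmbedding(s)
  sig <- sessionSignal(s)[roiIds(e), ]
  ph <- computePhase(sig, e)
  set.seed(33)
  w <- runif(length(wrappedPhase(ph)), -pi, pi)
  shuffled <- methods::new("PhaseTrace", wrapped = w,
                           unwrapped = unwrapPhase(w),
                           vectorNorm = phaseVectorNorm(ph), rate = ph@rate)
  profS <- tryCatch(phaseZeroedProfile(sig, e, shuffled),
                    error = function(e) NULL)
  if (is.null(profS)) succeed("flat profile rejected by FWHM estimator")
  else {
    peak <- max(phaseZeroedProfile(sig, e, ph)@mean)
    expect_lt(diff(range(profS@mean)), 0.05 * peak)
  }
})

test_that("FWHM: closed form pi for raised cosine, grid oracle for von Mises", {
  bins <- -pi + 2 * pi / 100 * (seq_len(100) - 0.5)
  expect_equal(estimateFwhm(0.5 * (1 + cos(bins)), bins), pi, tolerance = 0.01)
  kappa <- 2
  vm <- exp(kappa * (cos(bins) - 1))
  dense <- seq(-pi, pi, length.out = 100000)
  dvm <- exp(kappa * (cos(dense) - 1))
  half <- min(dvm) + (max(dvm) - min(dvm)) / 2
  oracle <- 2 * abs(dense[which.min(abs(dvm - half))])
  expect_equal(estimateFwhm(vm, bins), oracle, tolerance = 2 * pi / 100)
  expect_error(estimateFwhm(rep(1, 100), bins), "flat")
})

test_that("tuning curves peak at each neuron's angle; partners sit pi apart", {
  s <- refCleanSession(2)
  e <- trueEmbedding(s)
  sig <- sessionSignal(s)[roiIds(e), ]
  ph <- computePhase(sig, e)
  tc <- suppressWarnings(tuningCurves(sig, ph))
  alpha <- ringAlpha(e)
  covered <- colSums(!is.na(tc$curves)) > 0
  peakAngle <- apply(tc$curves, 1, function(y) {
    tc$phaseBins[which.max(replace(y, is.na(y), -Inf))]
  })
  binW <- 2 * pi / length(tc$phaseBins)
  err <- abs(circDist(peakAngle, unname(alpha)))
  expect_lt(median(err), 2 * binW)
  # anticorrelated partner at a pi angle
  i <- which.min(abs(alpha - 0))
  j <- which.min(abs(circDist(alpha, alpha[i] + pi)))
  expect_lt(abs(abs(circDist(unname(peakAngle[i]), unname(peakAngle[j]))) - pi),
            3 * binW)
  # constant-activity ROI gives an undefined FWHM
  flat <- zTraces(matrix(1, 2, length(wrappedPhase(ph))))
  tcF <- suppressWarnings(tuningCurves(flat, ph))
  expect_true(all(is.na(tcF$fwhm)))
})
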