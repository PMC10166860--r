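test_that("swim sequence respects rate and degenerate mixture settings", {
  expect_identical(nrow(simulateSwimSequence(sessionParams(swimRateHz = 0))), 0L)
  set.seed(1)
  ev <- simulateSwimSequence(sessionParams(lateralityCentralWeight = 1,
                                           durationS = 2000, swimRateHz = 0.2))
  expect_true(all(ev$swim_class == "forward"))
  expect_lt(max(abs(ev$laterality)), 5 * 0.1)  # central component only
})

test_that("swim mixture proportions match the generating weights within 3 s.e.", {
  set.seed(2)
  p <- sessionParams(durationS = 6000, swimRateHz = 2,
                     boutRefractoryS = 0.5)
  ev <- simulateSwimSequence(p)
  n <- nrow(ev)
  expect_gt(n, 3000)
  wC <- p@lateralityCentralWeight
  for (cls in c("forward", "left", "right")) {
    w <- if (cls == "forward") wC else (1 - wC) / 2
    se <- sqrt(w * (1 - w) / n)
    expect_lt(abs(mean(ev$swim_class == cls) - w), 3 * se)
  }
  # class labels agree with the generating component's sign convention
  expect_gt(median(ev$laterality[ev$swim_class == "right"]), 0)
  expect_lt(median(ev$laterality[ev$swim_class == "left"]), 0)
})

test_that("synthetic tail trace is invertible by the behavior module", {
  p <- sessionParams(tailNoiseSd = 0)
  expect_identical(sum(abs(synthesizeTailTrace(
    data.frame(onset_s = numeric(), offset_s = numeric(),
               laterality = numeric()), p)@angle)), 0)
  ev <- data.frame(onset_s = 1, offset_s = 1.25, laterality = 0.5)
  tail <- synthesizeTailTrace(ev, p)
  w70 <- round(0.07 * p@behaviorRateHz)
  i0 <- floor(1 * p@behaviorRateHz) + 1
  expect_equal(mean(tail@angle[i0:(i0 + w70 - 1)]), 0.5, tolerance = 0.01)
  det <- detectSwims(tail)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$onset_s - 1), 0.025)
  expect_equal(det$laterality, 0.5, tolerance = 0.05)
})

test_that("overlapping bouts are merged with a warning", {
  p <- sessionParams(tailNoiseSd = 0)
  ev <- data.frame(onset_s = c(1, 1.1), offset_s = c(1.3, 1.4),
                   laterality = c(0.5, -0.5))
  expect_warning(synthesizeTailTrace(ev, p), "merged")
})

test_that("ring ROI placement obeys the anatomical angle convention", {
  set.seed(3)
  roi <- placeRingRois(sessionParams(positionJitterUm = 0))
  ring <- roi[roi$is_ring, ]
  left <- ring[which.min(abs(ring$true_alpha - pi / 2)), ]
  expect_gt(left$lr, 0)                       # alpha = +pi/2 is on the left
  expect_lt(abs(left$rc), 1e-6)               # at the rostro-caudal center
  caudal <- ring[which.min(abs(ring$true_alpha)), ]
  expect_lt(caudal$rc, 0)                     # alpha = 0 is caudal-most
  expect_equal(min(ring$rc), caudal$rc, tolerance = 1e-9)
  anat <- atan2(ring$lr, -ring$rc)
  expect_gt(fisherLeeCorrelation(ring$true_alpha, anat), 0.99)
  # distractors sit outside the ring ellipse
  dis <- roi[!roi$is_ring, ]
  expect_true(all(sqrt(dis$lr^2 + dis$rc^2) > 30))
})

test_that("rendered calcium follows the tuning curve ground truth", {
  p <- sessionParams(noiseSd = 0, calciumTauS = 1e-9, swimRateHz = 0,
                     distractorFraction = 0, positionJitterUm = 0)
  roi <- placeRingRois(p)
  nF <- round(p@durationS * p@imagingRateHz)
  # phase parked at ROI k's preferred angle: that ROI is maximal and constant
  k <- 10
  truth <- methods::new("GroundTruth",
                        truePhase = rep(roi$true_alpha[k], nF),
                        trueHeading = numeric(0), trueAlpha = roi$true_alpha,
                        swimEvents = data.frame(onset_s = numeric(),
                                                laterality = numeric(),
                                                swim_class = character()))
  tr <- renderCalcium(truth, roi, p)
  v <- traceValues(tr)
  expect_equal(unname(v[k, ]), rep(1, nF), tolerance = 1e-9)
  expect_true(all(v[k, ] >= apply(v, 2, max) - 1e-9))
  # raised cosine: minimum over a full revolution is 0
  truth2 <- methods::new("GroundTruth",
                         truePhase = seq(-pi, pi, length.out = nF),
                         trueHeading = numeric(0), trueAlpha = roi$true_alpha,
                         swimEvents = truth@swimEvents)
  v2 <- traceValues(renderCalcium(truth2, roi, p))
  expect_lt(max(abs(apply(v2, 1, min))), 1e-6)
})

test_that("sessions are deterministic under a fixed seed and vary across seeds", {
  a <- simulateSession(sessionParams(seed = 11, durationS = 120))
  b <- simulateSession(sessionParams(seed = 11, durationS = 120))
  c <- simulateSession(sessionParams(seed = 12, durationS = 120))
  expect_identical(traceValues(sessionTraces(a)), traceValues(sessionTraces(b)))
  expect_identical(sessionTruth(a)@swimEvents, sessionTruth(b)@swimEvents)
  expect_false(identical(sessionTruth(a)@swimEvents$onset_s,
                         sessionTruth(c)@swimEvents$onset_s))
})

test_that("true phase increments only at swim onsets and is constant between", {
  s <- refSession(1)
  tp <- sessionTruth(s)@truePhase
  ev <- sessionTruth(s)@swimEvents
  stepFrames <- ceiling(ev$onset_s * 5) + 1
  changed <- which(diff(tp) != 0) + 1
  expect_true(all(changed %in% stepFrames))
  expect_equal(tp[length(tp)] - tp[1], -1 * sum(ev$laterality),
               tolerance = 1e-9)
})

test_that("behavior round trip recovers >= 95% of swims with correct class", {
  s <- refSession(1)
  ev <- sessionTruth(s)@swimEvents
  det <- detectSwims(sessionTail(s))
  fit <- fitTrimodal(det$laterality)
  det <- classifySwims(det, fit)
  # match detected events to truth by onset
  matched <- vapply(ev$onset_s, function(o) {
    i <- which.min(abs(det$onset_s - o))
    if (abs(det$onset_s[i] - o) < 0.05) i else NA_integer_
  }, integer(1))
  expect_gte(mean(!is.na(matched)), 0.95)
  agree <- det$swim_class[matched[!is.na(matched)]] ==
    ev$swim_class[!is.na(matched)]
  expect_gte(mean(agree), 0.95)
})
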