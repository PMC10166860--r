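ringMatrix <- function(nRoi = 16, nF = 720, amp = 1) {
  alpha <- -pi + 2 * pi * seq_len(nRoi) / nRoi
  phi <- seq(-pi, pi, length.out = nF + 1)[-1]   # uniform full coverage
  list(values = amp * outer(alpha, phi, function(a, p) cos(p - a)),
       alpha = alpha, phi = phi)
}

test_that("state-space PCA: a rank-2 ring explains 100%, noise lowers it", {
  r <- ringMatrix()
  p <- pcaStateSpace(zTraces(r$values), k = 2)
  expect_equal(sum(p$varianceFraction), 1, tolerance = 1e-9)
  withNoise <- rbind(r$values, rnorm(ncol(r$values)))
  p2 <- pcaStateSpace(zTraces(withNoise), k = 2)
  expect_lt(sum(p2$varianceFraction), 1)
  expect_gt(sum(p2$varianceFraction), 0.8)
  expect_error(pcaStateSpace(zTraces(r$values[1:2, 1:1]), k = 2), "k ROIs|rank")
})

test_that("explained variance follows the analytic signal/noise budget", {
  set.seed(21)
  r <- ringMatrix(nRoi = 40, nF = 3000)
  sigma <- 0.3
  noisy <- r$values + matrix(rnorm(length(r$values), 0, sigma), nrow(r$values))
  p <- pcaStateSpace(zTraces(noisy), k = 2)
  sig2 <- mean(r$values^2)   # per-ROI signal variance (cosine, power 1/2)
  predicted <- sig2 / (sig2 + sigma^2)
  expect_equal(sum(p$varianceFraction), predicted, tolerance = 0.03)
})

test_that("neuron embedding puts a noiseless uniform ring on an exact circle", {
  r <- ringMatrix()
  emb <- pcaNeuronEmbedding(zTraces(r$values))
  radii <- sqrt(rowSums(sweep(emb$coords, 2, colMeans(emb$coords))^2))
  expect_lt(sd(radii) / mean(radii), 1e-6)
  # duplicated ROI lands on a coincident point
  dup <- rbind(r$values, r$values[3, ])
  emb2 <- pcaNeuronEmbedding(zTraces(dup))
  expect_equal(emb2$coords[nrow(dup), ], emb2$coords[3, ], tolerance = 1e-9)
})

test_that("hyper circle fit is exact on circles and equivariant to rotation", {
  th <- seq(0, 2 * pi, length.out = 37)[-1]
  pts <- cbind(2 + 3 * cos(th), -1 + 3 * sin(th))
  cf <- fitCircle(pts)
  expect_equal(cf@center, c(2, -1), tolerance = 1e-9)
  expect_equal(cf@radius, 3, tolerance = 1e-9)
  rot <- pi / 6
  R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2, byrow = TRUE)
  cf2 <- fitCircle(pts %*% t(R))
  expect_equal(cf2@center, as.numeric(R %*% c(2, -1)), tolerance = 1e-9)
  expect_equal(cf2@radius, 3, tolerance = 1e-9)
  expect_error(fitCircle(cbind(1:10, 2 * (1:10))), "collinear")
})

test_that("hyper fit agrees with the iterative geometric fit on noisy circles", {
  set.seed(22)
  for (k in 1:50) {
    th <- runif(100, 0, 2 * pi)
    r0 <- runif(1, 1, 5)
    c0 <- runif(2, -3, 3)
    pts <- cbind(c0[1] + r0 * cos(th), c0[2] + r0 * sin(th)) +
      matrix(rnorm(200, 0, 0.05 * r0), 100, 2)
    h <- fitCircle(pts)
    g <- fitCircleGeometric(pts)
    expect_lt(sqrt(sum((h@center - g@center)^2)), 0.02 * r0)
    expect_lt(abs(h@radius - g@radius), 0.02 * r0)
  }
})

alignedFixture <- function(nRoi = 24, jitter = 0) {
  alpha <- -pi + 2 * pi * seq_len(nRoi) / nRoi
  roi <- data.frame(roi_id = sprintf("R%03d", seq_len(nRoi)),
                    lr = 30 * sin(alpha) + rnorm(nRoi, 0, jitter),
                    rc = -30 * cos(alpha) + rnorm(nRoi, 0, jitter))
  coords <- cbind(cos(alpha), sin(alpha))
  rownames(coords) <- roi$roi_id
  list(alpha = alpha, roi = roi, coords = coords)
}

test_that("alignment is identity for an already-aligned embedding", {
  f <- alignedFixture()
  emb <- alignEmbedding(f$coords, f$roi)
  expect_false(emb@transform$reflection)
  expect_lt(abs(emb@transform$rotation), 1e-9)
  expect_lt(sum(abs(emb@anchorAngles)), 1e-6)
  expect_equal(unname(ringAlpha(emb)), f$alpha, tolerance = 1e-6)
})

test_that("alignment undoes a known rotation and detects a reflection", {
  f <- alignedFixture()
  rot <- 30 * pi / 180
  R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2, byrow = TRUE)
  emb <- alignEmbedding(f$coords %*% t(R), f$roi)
  expect_equal(emb@transform$rotation, -rot, tolerance = 0.1 * pi / 180 + 1e-9)
  expect_false(emb@transform$reflection)
  mir <- f$coords; mir[, 2] <- -mir[, 2]
  embM <- alignEmbedding(mir, f$roi)
  expect_true(embM@transform$reflection)
  expect_equal(unname(ringAlpha(embM)), f$alpha, tolerance = 1e-6)
})

test_that("alpha assignment is equivariant to rotating the anatomy", {
  f <- alignedFixture()
  delta <- 0.4
  roiRot <- f$roi
  # advance every ROI's anatomical angle by delta: assigned alpha follows
  anat <- atan2(f$roi$lr, -f$roi$rc) + delta
  roiRot$lr <- 30 * sin(anat)
  roiRot$rc <- -30 * cos(anat)
  emb0 <- alignEmbedding(f$coords, f$roi)
  emb1 <- alignEmbedding(f$coords, roiRot)
  shift <- wrapToPi(ringAlpha(emb1) - ringAlpha(emb0))
  expect_equal(unname(shift), rep(delta, nrow(f$roi)),
               tolerance = 0.1 * pi / 180 + 1e-9)
  expect_error(alignEmbedding(f$coords, transform(f$roi, lr = 0, rc = 0)),
               "unpolarized")
})

test_that("anatomy statistics: perfect rings give rho 1, shuffles are null", {
  f <- alignedFixture()
  emb <- alignEmbedding(f$coords, f$roi)
  st <- anatomyStats(emb, f$roi, nShuffles = 100)
  expect_equal(st$rho_t, 1, tolerance = 1e-9)
  expect_lt(st$sinusoidResiduals[["lr"]], min(st$shuffleResiduals[, "lr"]))
  # null coverage: independent angles give small |rho| most of the time
  set.seed(23)
  nullRho <- replicate(100, {
    fisherLeeCorrelation(runif(200, -pi, pi), runif(200, -pi, pi))
  })
  expect_gte(mean(abs(nullRho) < 0.2), 0.95)
})

test_that("embedding of synthetic sessions lands on a near-unit circle", {
  res <- refAnalysis(1)
  cf <- fitCircle(rpcCoords(res$embedding))
  expect_lt(sqrt(sum(cf@center^2)), 0.02)
  expect_lt(abs(cf@radius - 1), 0.02)
  radii <- sqrt(rowSums(rpcCoords(res$embedding)^2))
  expect_lt(sd(radii) / mean(radii), 0.15)
})
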