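#' @include AllClasses.R utils-circular.R
NULL

#' PCA of the population state space
#'
#' Principal components with time points as observations in ROI space; the
#' ring network's trajectory is a circle in the plane of the first two
#' components, which capture most of the variance.
#'
#' @param traces a preprocessed [RoiTraces-class] with >= k ROIs.
#' @param k number of components to return.
#' @return list with `scores` (frames x k), `varianceFraction` (length k)
#'   and the ROI loadings `rotation`.
#' @export
pcaStateSpace <- function(traces, k = 2) {
  X <- t(traceValues(traces))
  if (ncol(X) < k) stop("need at least k ROIs")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  if (length(ev) < k || ev[k] <= 1e-12 * ev[1]) {
    stop(sprintf("trace matrix has rank < %d", k))
  }
  list(scores = p$x[, seq_len(k), drop = FALSE],
       varianceFraction = (ev / sum(ev))[seq_len(k)],
       rotation = p$rotation[, seq_len(k), drop = FALSE])
}

#' PCA embedding of neurons
#'
#' The transposed projection: ROIs are the observations and time points the
#' variables, so each ROI maps to a point in the plane of the first two
#' components. Ring neurons with sinusoidal tuning land on a circle whose
#' angle tracks their tuning preference.
#'
#' @param traces a preprocessed [RoiTraces-class] with >= 3 ROIs.
#' @return list with `coords` (ROIs x 2, rownames = ROI ids) and
#'   `varianceFraction`.
#' @export
pcaNeuronEmbedding <- function(traces) {
  X <- traceValues(traces)
  if (nrow(X) < 3) stop("need at least 3 ROIs")
  p <- tryCatch(stats::prcomp(X, center = TRUE, scale. = FALSE),
                error = function(e) stop("degenerate covariance: ", conditionMessage(e)))
  ev <- p$sdev^2
  if (length(ev) < 2 || ev[2] <= 1e-12 * ev[1]) {
    stop("degenerate covariance: neuron embedding has rank < 2")
  }
  coords <- p$x[, 1:2, drop = FALSE]
  rownames(coords) <- rownames(X)
  list(coords = coords, varianceFraction = (ev / sum(ev))[1:2])
}

#' Algebraic circle fit (hyperaccurate)
#'
#' Hyper least-squares circle fit: solves the generalized eigenproblem
#' M A = eta H A for the algebraic circle parameters, which is unbiased to
#' leading order for small noise. Exact circles are recovered to machine
#' precision.
#'
#' @param points n x 2 matrix, n >= 3, not collinear.
#' @return a [CircleFit-class].
#' @export
fitCircle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  x <- points[, 1] - mx
  y <- points[, 2] - my
  cv <- stats::cov(cbind(x, y))
  e <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (e[2] <= 1e-12 * max(e[1], 1e-300)) stop("points are collinear")
  z <- x^2 + y^2
  Z <- cbind(z, x, y, 1)
  M <- crossprod(Z) / nrow(Z)
  zbar <- mean(z)
  H <- matrix(c(8 * zbar, 0, 0, 2,
                0, 1, 0, 0,
                0, 0, 1, 0,
                2, 0, 0, 0), 4, 4, byrow = TRUE)
  E <- eigen(solve(H, M))
  vals <- Re(E$values)
  vals[vals < -1e-9] <- Inf      # discard spurious negative eigenvalues
  A <- Re(E$vectors[, which.min(abs(vals))])
  if (abs(A[1]) < 1e-14) stop("degenerate algebraic solution (points collinear?)")
  cx <- -A[2] / (2 * A[1])
  cy <- -A[3] / (2 * A[1])
  r2 <- cx^2 + cy^2 - A[4] / A[1]
  if (r2 <= 0) stop("circle fit failed: non-positive squared radius")
  methods::new("CircleFit", center = c(cx + mx, cy + my), radius = sqrt(r2))
}

#' Geometric (iterative) circle fit
#'
#' Minimizes the sum of squared orthogonal distances to the circle by
#' nonlinear optimization over the center (the optimal radius given a center
#' is the mean distance). Serves as an independent reference for
#' [fitCircle()].
#'
#' @inheritParams fitCircle
#' @return a [CircleFit-class].
#' @export
fitCircleGeometric <- function(points) {
  points <- as.matrix(points)
  loss <- function(c0) {
    d <- sqrt((points[, 1] - c0[1])^2 + (points[, 2] - c0[2])^2)
    sum((d - mean(d))^2)
  }
  init <- colMeans(points)
  opt <- stats::optim(init, loss, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  d <- sqrt((points[, 1] - opt$par[1])^2 + (points[, 2] - opt$par[2])^2)
  methods::new("CircleFit", center = opt$par, radius = mean(d))
}

#' Align a neuron embedding to the anatomical convention
#'
#' Normalizes the 2-D neuron embedding to a unit circle centered on the
#' origin (via the hyper circle fit), then rotates (0.1 degree grid) and
#' optionally reflects it so that two anatomy-weighted anchor vectors match
#' their target directions: the rostral anchor (embedding coordinates
#' weighted by the centered rostro-caudal coordinate) should point to +-pi
#' and the rightward anchor (weighted by the centered right-left coordinate)
#' to -pi/2. The transform minimizing |theta1| + |theta2|, the two angular
#' misfits, is applied, and each ROI is assigned its ring angle alpha =
#' atan2(y, x) in (-pi, pi] (caudal = 0, left = +pi/2, right = -pi/2).
#'
#' @param coords ROIs x 2 embedding coordinates (rownames = ROI ids), e.g.
#'   from [pcaNeuronEmbedding()].
#' @param roi data.frame with anatomical columns `lr` and `rc` (and
#'   rownames or `roi_id` matching `coords`).
#' @param gridDeg rotation search resolution, degrees.
#' @return an [RpcEmbedding-class].
#' @export
alignEmbedding <- function(coords, roi, gridDeg = 0.1) {
  coords <- as.matrix(coords)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- sprintf("R%03d", seq_len(nrow(coords)))
  if (!is.null(roi$roi_id)) rownames(roi) <- roi$roi_id
  roi <- roi[ids, , drop = FALSE]
  cf <- fitCircle(coords)
  norm <- sweep(coords, 2, cf@center) / cf@radius
  wRos <- roi$rc - mean(roi$rc)      # rostral positive
  wRight <- -(roi$lr - mean(roi$lr)) # right positive
  aRos <- colSums(wRos * norm)
  aRight <- colSums(wRight * norm)
  tol <- 1e-8 * nrow(coords)
  if (sqrt(sum(aRos^2)) < tol || sqrt(sum(aRight^2)) < tol) {
    stop("anchor vector magnitude below tolerance: ROI set is anatomically unpolarized")
  }
  angRos <- atan2(aRos[2], aRos[1])
  angRight <- atan2(aRight[2], aRight[1])
  deltas <- seq(-180, 180 - gridDeg, by = gridDeg) * pi / 180
  best <- NULL
  for (s in c(1, -1)) {   # s = -1: reflection about the x-axis
    t1 <- abs(wrapToPi(s * angRos + deltas - pi))
    t2 <- abs(wrapToPi(s * angRight + deltas + pi / 2))
    objective <- t1 + t2
    i <- which(objective == min(objective))
    i <- i[which.min(abs(deltas[i]))]   # tie-break toward smaller rotation
    cand <- list(obj = objective[i], delta = deltas[i], s = s,
                 theta = c(wrapToPi(s * angRos + deltas[i] - pi),
                           wrapToPi(s * angRight + deltas[i] + pi / 2)))
    if (is.null(best) || cand$obj < best$obj - 1e-12) best <- cand
  }
  refl <- best$s == -1
  pts <- norm
  if (refl) pts[, 2] <- -pts[, 2]
  R <- matrix(c(cos(best$delta), -sin(best$delta),
                sin(best$delta), cos(best$delta)), 2, 2, byrow = TRUE)
  pts <- pts %*% t(R)
  alpha <- wrapToPi(atan2(pts[, 2], pts[, 1]))
  methods::new("RpcEmbedding", coords = pts, alpha = as.numeric(alpha),
               transform = list(center = cf@center, radius = cf@radius,
                                rotation = best$delta, reflection = refl),
               anchorAngles = as.numeric(best$theta), roiIds = ids)
}

#' Build the rotated-PC embedding from traces and anatomy
#'
#' Convenience wrapper: [pcaNeuronEmbedding()] then [alignEmbedding()].
#'
#' @param traces a preprocessed [RoiTraces-class] (ring ROIs only).
#' @param roi anatomy table (see [alignEmbedding()]); defaults to
#'   `roiInfo(traces)`.
#' @param ... passed to [alignEmbedding()].
#' @return an [RpcEmbedding-class].
#' @export
buildEmbedding <- function(traces, roi = roiInfo(traces), ...) {
  emb <- pcaNeuronEmbedding(traces)
  alignEmbedding(emb$coords, roi, ...)
}

#' Anatomical organization statistics of the ring
#'
#' Fisher-Lee circular correlation between the ring angle alpha and the
#' anatomical angle atan2(lr, -rc), plus per-axis sinusoid fits
#' coordinate ~ a sin(alpha + phi0) + c with residuals compared to a shuffle
#' obtained by randomly reassigning anatomical coordinates to ROIs.
#'
#' @param embedding an [RpcEmbedding-class].
#' @param roi anatomy table with `lr`, `rc` (rownames or `roi_id` matching).
#' @param nShuffles shuffle count.
#' @return list with `rho_t`, `anatomicalAngle`, `sinusoidResiduals`
#'   (named, per axis), `shuffleResiduals` (nShuffles x 2 matrix).
#' @export
anatomyStats <- function(embedding, roi, nShuffles = 1000) {
  ids <- embedding@roiIds
  if (length(ids) < 8) stop("need at least 8 ROIs")
  if (!is.null(roi$roi_id)) rownames(roi) <- roi$roi_id
  roi <- roi[ids, , drop = FALSE]
  alpha <- embedding@alpha
  anat <- atan2(roi$lr, -roi$rc)
  rho <- fisherLeeCorrelation(alpha, anat)
  basis <- cbind(sin(alpha), cos(alpha))
  resid2 <- function(yv) sum(stats::lm.fit(cbind(1, basis), yv)$residuals^2)
  obs <- c(lr = resid2(roi$lr), rc = resid2(roi$rc))
  shuf <- matrix(NA_real_, nShuffles, 2,
                 dimnames = list(NULL, c("lr", "rc")))
  for (b in seq_len(nShuffles)) {
    p <- sample.int(length(ids))
    shuf[b, ] <- c(resid2(roi$lr[p]), resid2(roi$rc[p]))
  }
  list(rho_t = rho, anatomicalAngle = stats::setNames(anat, ids),
       sinusoidResiduals = obs, shuffleResiduals = shuf,
       pShuffle = c(lr = mean(shuf[, 1] <= obs[1]),
                    rc = mean(shuf[, 2] <= obs[2])))
}
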