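#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @export
wrapToPi <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  # map the -pi representative to +pi so the interval is (-pi, pi]
  w[w <= -pi + 1e-12 & !is.na(w)] <- pi
  w
}

#' Circular distance between two angle vectors
#'
#' @param a,b angles in radians (recycled).
#' @return signed angular difference a - b wrapped to (-pi, pi].
#' @export
circDist <- function(a, b) wrapToPi(a - b)

#' Circular root-mean-square error
#'
#' RMSE of the wrapped angular differences; invariant to joint 2*pi shifts.
#'
#' @param a,b angle vectors in radians, same length.
#' @return RMSE in radians.
#' @export
circRmse <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(mean(circDist(a, b)^2))
}

#' Fisher-Lee circular-circular correlation coefficient
#'
#' T-linear association between two circular variables,
#' rho_T = sum_{i<j} sin(t_i - t_j) sin(p_i - p_j) /
#'         sqrt(sum_{i<j} sin^2(t_i - t_j) * sum_{i<j} sin^2(p_i - p_j)).
#' Computed in O(n) through the identity
#' sum_{i,j} sin(t_i - t_j) sin(p_i - p_j) =
#'   (|sum e^{i(t - p)}|^2 - |sum e^{i(t + p)}|^2) / 2
#' and sum_{i,j} sin^2(t_i - t_j) = (n^2 - |sum e^{2 i t}|^2) / 2.
#'
#' @param theta,phi angle vectors in radians, equal length, n >= 3.
#' @return correlation in [-1, 1].
#' @export
fisherLeeCorrelation <- function(theta, phi) {
  stopifnot(length(theta) == length(phi), length(theta) >= 3)
  n <- length(theta)
  modsq <- function(a) sum(cos(a))^2 + sum(sin(a))^2
  num <- (modsq(theta - phi) - modsq(theta + phi)) / 2
  d1 <- (n^2 - modsq(2 * theta)) / 2
  d2 <- (n^2 - modsq(2 * phi)) / 2
  if (d1 <= 0 || d2 <= 0) {
    stop("Fisher-Lee correlation undefined: an input is angularly degenerate")
  }
  num / sqrt(d1 * d2)
}

#' Rayleigh test of circular uniformity
#'
#' @param angles radians.
#' @return list with mean resultant length `rbar`, statistic `z = n rbar^2`
#'   and the standard large-sample p-value approximation.
#' @export
rayleighTest <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("need at least 2 angles")
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  z <- n * rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (rbar * n)^2)) - (1 + 2 * n))
  list(rbar = rbar, statistic = z, p.value = min(1, p), n = n)
}

#' Watson-Wheeler test for homogeneity of circular samples
#'
#' Uniform-scores (circular rank) test across two or more groups.
#'
#' @param angles radians.
#' @param group factor-like group labels, same length as `angles`.
#' @return list with statistic `W`, degrees of freedom and chi-square p-value.
#' @export
watsonWheelerTest <- function(angles, group) {
  group <- as.factor(group)
  stopifnot(length(angles) == length(group))
  n <- length(angles)
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups")
  gamma <- 2 * pi * rank(angles, ties.method = "average") / n
  W <- 0
  for (lev in levels(group)) {
    idx <- group == lev
    nk <- sum(idx)
    if (nk < 1) next
    W <- W + (sum(cos(gamma[idx]))^2 + sum(sin(gamma[idx]))^2) / nk
  }
  W <- 2 * W
  df <- 2 * (k - 1)
  list(statistic = W, df = df, p.value = stats::pchisq(W, df, lower.tail = FALSE))
}
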