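#' Discretized label grid for distribution regression
#'
#' Partitions a water-potential range into \code{k = ceiling((hi - lo) / l)}
#' intervals of length \code{l} (MPa) and records the interval centers
#' \eqn{l_k = lo + (j + 0.5) l}.
#'
#' @param lo,hi Range endpoints in MPa, \code{lo < hi}.
#' @param l Interval length in MPa, > 0.
#' @return A list of class \code{label_grid} with fields \code{l}, \code{k},
#'   \code{centers}, \code{lo}, \code{hi} (hi after rounding up to a whole
#'   number of intervals).
#' @export
#' @examples
#' g <- label_grid(-1, 0, 0.25)
#' g$centers  # -0.875 -0.625 -0.375 -0.125
label_grid <- function(lo, hi, l) {
  if (!(lo < hi)) stop("invalid range: lo must be < hi")
  if (l <= 0) stop("interval length l must be > 0")
  k <- as.integer(ceiling((hi - lo) / l - 1e-12))
  centers <- lo + (seq_len(k) - 0.5) * l
  structure(list(l = l, k = k, centers = centers, lo = lo, hi = lo + k * l),
            class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  cat(sprintf("<label_grid> k=%d intervals of l=%g MPa on [%g, %g]\n",
              x$k, x$l, x$lo, x$hi))
  invisible(x)
}

#' Encode a scalar label as a discrete Gaussian distribution
#'
#' Evaluates a Gaussian kernel of spread \code{sigma} centred at the true
#' label \code{y} at every interval center and renormalizes so the
#' probabilities sum to 1 (the continuous density does not sum to 1 on a
#' discrete grid).
#'
#' @param y Label(s) in MPa; scalar or vector.
#' @param grid A \code{\link{label_grid}}.
#' @param sigma Gaussian spread in MPa, > 0.
#' @return A probability vector of length \code{grid$k}, or a matrix with
#'   one row per element of \code{y}.
#' @export
encode_label_distribution <- function(y, grid, sigma) {
  stopifnot(inherits(grid, "label_grid"))
  if (sigma <= 0) stop("sigma must be > 0")
  P <- exp(-outer(y, grid$centers, "-")^2 / (2 * sigma^2))
  P <- P / rowSums(P)
  if (length(y) == 1L) drop(P) else P
}

#' Mean Kullback-Leibler divergence between label distributions
#'
#' \eqn{(1/B) \sum_i \sum_k p_{ik} \ln(p_{ik} / \hat p_{ik})}, with the
#' predicted probabilities clamped below at \code{epsilon} and the
#' convention \eqn{0 \ln(0/\cdot) = 0}. Non-negative; 0 iff the
#' distributions match (up to the clamp).
#'
#' @param p True label distributions: vector or matrix (rows = samples).
#' @param phat Predicted distributions, same shape.
#' @param epsilon Clamp for \code{phat} inside the logarithm.
#' @return Scalar mean KL divergence (nats).
#' @export
#' @examples
#' kl_loss(c(1, 0), c(0.5, 0.5))  # log(2)
kl_loss <- function(p, phat, epsilon = 1e-8) {
  if (is.null(dim(p))) p <- matrix(p, 1L)
  if (is.null(dim(phat))) phat <- matrix(phat, 1L)
  if (!all(dim(p) == dim(phat))) stop("p and phat shapes differ")
  terms <- ifelse(p > 0, p * (log(p) - log(pmax(phat, epsilon))), 0)
  sum(terms) / nrow(p)
}

#' Decode a predicted distribution to a point prediction
#'
#' The expectation of the predicted distribution over the interval centers,
#' \eqn{\hat y = \sum_k \hat p_k l_k}; always a convex combination, so the
#' result lies inside [min center, max center].
#'
#' @param phat Probability vector (or matrix, rows = samples) over the grid.
#' @param grid A \code{\link{label_grid}}.
#' @return Predicted value(s) in MPa.
#' @export
expectation_decode <- function(phat, grid) {
  stopifnot(inherits(grid, "label_grid"))
  if (is.null(dim(phat))) phat <- matrix(phat, 1L)
  if (ncol(phat) != grid$k) stop("distribution length differs from grid")
  s <- rowSums(phat)
  if (any(abs(s - 1) > 1e-6)) stop("phat rows must sum to 1")
  drop(phat %*% grid$centers)
}

#' Mean squared error regression loss
#'
#' @param y True values.
#' @param yhat Predicted values, same length.
#' @return \eqn{(1/B) \sum_i (y_i - \hat y_i)^2}.
#' @export
regression_loss <- function(y, yhat) {
  if (length(y) == 0L) stop("empty batch")
  if (length(y) != length(yhat)) stop("length mismatch")
  mean((y - yhat)^2)
}

#' Combined training objective
#'
#' \eqn{L_{total} = C \cdot L_{reg} + L_{ld} + \eta \sum_i \theta_i^2}: the
#' regression loss weighted by \code{C}, plus the distribution (KL) loss,
#' plus an L2 penalty over all trainable parameters.
#'
#' @param reg Regression loss value.
#' @param ld Label-distribution (KL) loss value.
#' @param params Parameter list (nested numeric arrays) for the L2 term;
#'   NULL for no penalty term.
#' @param cfg A \code{\link{darn_config}} supplying \code{C} and \code{eta}.
#' @return Scalar total loss.
#' @export
total_loss <- function(reg, ld, params = NULL, cfg = darn_config()) {
  stopifnot(is.finite(reg), is.finite(ld))
  pen <- if (is.null(params) || cfg$eta == 0) 0 else
    cfg$eta * par_sum_sq(params)
  cfg$C * reg + ld + pen
}

#' Distribution-regression configuration
#'
#' @param sigma Gaussian label-encoding spread in MPa (default 0.4).
#' @param l Label-grid interval length in MPa (default 0.15).
#' @param C Regression-loss coefficient in the combined objective
#'   (default 1).
#' @param eta L2 regularization weight (default 1e-5).
#' @param epsilon Clamp inside the KL logarithm (default 1e-8).
#' @param pad_sigmas Grid padding beyond the training label range, in units
#'   of sigma (default 3): the grid spans
#'   [min(y) - pad_sigmas * sigma, max(y) + pad_sigmas * sigma].
#' @return A list of class \code{darn_config}.
#' @export
darn_config <- function(sigma = 0.4, l = 0.15, C = 1, eta = 1e-5,
                        epsilon = 1e-8, pad_sigmas = 3) {
  stopifnot(sigma > 0, l > 0, C >= 0, eta >= 0, epsilon > 0, pad_sigmas >= 0)
  structure(list(sigma = sigma, l = l, C = C, eta = eta, epsilon = epsilon,
                 pad_sigmas = pad_sigmas),
            class = "darn_config")
}
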