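# Compound BCE + Dice objective and its analytic per-voxel gradient, the
# quantity backpropagated into the network output during training.

checkPredTarget <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target must have identical shape")
}

#' Binary cross-entropy loss
#'
#' \eqn{-(1/N) \sum_i [y_i \log \hat y_i + (1-y_i) \log(1-\hat y_i)]} over
#' all N voxels. Predictions are clipped to \code{[eps, 1-eps]} internally
#' so saturated sigmoid outputs yield a finite loss.
#'
#' @param pred probabilities in [0, 1] (array/matrix/vector).
#' @param target binary values in \{0, 1\}, same shape.
#' @param eps clipping constant.
#' @return Scalar loss (>= 0).
#' @export
bceLoss <- function(pred, target, eps = 1e-7) {
  checkPredTarget(pred, target)
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Dice loss
#'
#' \eqn{1 - (2\sum y \hat y + s) / (\sum y + \sum \hat y + s)} with
#' smoothing constant s in numerator and denominator, so two empty masks
#' score a perfect 0.
#'
#' @inheritParams bceLoss
#' @param smooth smoothing constant (>= 0).
#' @return Scalar loss in [0, 1].
#' @export
diceLoss <- function(pred, target, smooth = 1e-6) {
  checkPredTarget(pred, target)
  1 - (2 * sum(target * pred) + smooth) /
    (sum(target) + sum(pred) + smooth)
}

#' Compound segmentation loss
#'
#' \eqn{L = \omega_1 L_{BCE} + \omega_2 L_{Dice}}; both weights default to
#' 0.5. During recurrent training the same form is applied per slice t and
#' the per-step losses are summed.
#'
#' @inheritParams bceLoss
#' @param weights a [LossWeights()].
#' @return Scalar loss (>= 0).
#' @export
combinedLoss <- function(pred, target, weights = LossWeights()) {
  weights@omega1 * bceLoss(pred, target) +
    weights@omega2 * diceLoss(pred, target, weights@smooth)
}

#' Analytic gradient of the compound loss
#'
#' Per-voxel derivative of [combinedLoss()] with respect to the predicted
#' probability:
#' \deqn{\partial L/\partial \hat y_j =
#'   -\frac{\omega_1}{N}\left[\frac{y_j}{\hat y_j} -
#'   \frac{1-y_j}{1-\hat y_j}\right]
#'   - \omega_2\left[\frac{2 y_j}{\Sigma} -
#'   \frac{2\sum_i y_i \hat y_i + s}{\Sigma^2}\right],\quad
#'   \Sigma = \sum_i (y_i + \hat y_i) + s,}
#' evaluated with the smoothing constant s placed consistently with
#' [diceLoss()]. This is what the training loop feeds into the network
#' backward pass; it is validated against central finite differences of the
#' loss itself.
#'
#' @param pred probabilities strictly inside (0, 1).
#' @param target binary values, same shape.
#' @param weights a [LossWeights()].
#' @return Per-voxel gradient, same shape as \code{pred}.
#' @export
lossGradient <- function(pred, target, weights = LossWeights()) {
  checkPredTarget(pred, target)
  if (any(pred <= 0) || any(pred >= 1))
    stop("lossGradient requires predictions strictly inside (0, 1)")
  N <- length(pred)
  gBCE <- -(target / pred - (1 - target) / (1 - pred)) / N
  s <- weights@smooth
  denom <- sum(target) + sum(pred) + s
  gDice <- -(2 * target / denom - (2 * sum(target * pred) + s) / denom^2)
  g <- weights@omega1 * gBCE + weights@omega2 * gDice
  if (!is.null(dim(pred))) dim(g) <- dim(pred)
  g
}
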