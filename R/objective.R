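#' Loss configuration
#'
#' @param smooth Dice smoothing constant k (default 1.0), which keeps the
#'   Dice term defined when both prediction and truth are empty.
#' @param clip probability clip applied before logarithms (default 1e-7).
#' @param reduction \code{"sum"} (cross-entropy summed over pixels) or
#'   \code{"mean"}; the Dice term is a ratio and is unaffected.
#' @export
loss_config <- function(smooth = 1.0, clip = 1e-7,
                        reduction = c("sum", "mean")) {
  if (smooth <= 0) stop("loss_config: smooth must be > 0")
  if (clip <= 0 || clip >= 0.5) stop("loss_config: clip must be in (0, 0.5)")
  structure(list(smooth = smooth, clip = clip,
                 reduction = match.arg(reduction)),
            class = "loss_config")
}

.check_pair <- function(y_pred, y_true) {
  if (length(y_pred) != length(y_true))
    stop("loss: prediction and truth lengths differ")
}

#' Binary cross-entropy
#'
#' \code{-sum(y * log(p) + (1 - y) * log(1 - p))} over pixels, with
#' predictions clipped away from 0 and 1 before the logarithms.
#'
#' @param y_pred predicted vessel probabilities in [0, 1].
#' @param y_true binary ground-truth labels.
#' @param clip probability clip.
#' @param reduction \code{"sum"} or \code{"mean"}.
#' @export
cross_entropy <- function(y_pred, y_true, clip = 1e-7,
                          reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  .check_pair(y_pred, y_true)
  p <- pmin(pmax(y_pred, clip), 1 - clip)
  ce <- -(y_true * log(p) + (1 - y_true) * log(1 - p))
  if (reduction == "sum") sum(ce) else mean(ce)
}

#' Gradient of the binary cross-entropy w.r.t. the predictions
#' @inheritParams cross_entropy
#' @export
cross_entropy_grad <- function(y_pred, y_true, clip = 1e-7,
                               reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  .check_pair(y_pred, y_true)
  p <- pmin(pmax(y_pred, clip), 1 - clip)
  g <- -y_true / p + (1 - y_true) / (1 - p)
  g[y_pred < clip | y_pred > 1 - clip] <- 0  # flat beyond the clip
  if (reduction == "mean") g <- g / length(g)
  g
}

#' Smoothed Dice loss
#'
#' \code{1 - (2 * sum(y * p) + k) / (sum(y) + sum(p) + k)}: one minus the
#' smoothed Dice overlap between predicted probabilities and binary truth.
#' Zero exactly when prediction equals truth on binary inputs (including
#' the all-empty case, thanks to the smoothing constant).
#'
#' @param y_pred predicted vessel probabilities in [0, 1].
#' @param y_true binary ground-truth labels.
#' @param smooth smoothing constant k (default 1.0).
#' @export
dice_loss <- function(y_pred, y_true, smooth = 1.0) {
  .check_pair(y_pred, y_true)
  num <- 2 * sum(y_true * y_pred) + smooth
  den <- sum(y_true) + sum(y_pred) + smooth
  1 - num / den
}

#' Gradient of the smoothed Dice loss w.r.t. the predictions
#' @inheritParams dice_loss
#' @export
dice_loss_grad <- function(y_pred, y_true, smooth = 1.0) {
  .check_pair(y_pred, y_true)
  num <- 2 * sum(y_true * y_pred) + smooth
  den <- sum(y_true) + sum(y_pred) + smooth
  (num - 2 * y_true * den) / den^2
}

#' Combined cross-entropy + Dice loss
#'
#' The training objective: the sum of the binary cross-entropy and the
#' smoothed Dice loss. The cross-entropy term responds to every pixel while
#' the Dice term targets overlap of the (rare) vessel class, countering the
#' vessel/background imbalance.
#'
#' @param y_pred predicted vessel probabilities.
#' @param y_true binary labels.
#' @param cfg a \code{\link{loss_config}}.
#' @export
combined_loss <- function(y_pred, y_true, cfg = loss_config()) {
  cross_entropy(y_pred, y_true, cfg$clip, cfg$reduction) +
    dice_loss(y_pred, y_true, cfg$smooth)
}

#' Gradient of the combined loss w.r.t. the predictions
#' @inheritParams combined_loss
#' @export
combined_loss_grad <- function(y_pred, y_true, cfg = loss_config()) {
  cross_entropy_grad(y_pred, y_true, cfg$clip, cfg$reduction) +
    dice_loss_grad(y_pred, y_true, cfg$smooth)
}
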