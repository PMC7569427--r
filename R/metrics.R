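#' Confusion counts for a binarized probability map
#'
#' Pixels with probability at or above the threshold are called vessel.
#' When a field-of-view mask is given, only pixels inside it are counted.
#'
#' @param prob_map numeric matrix of vessel probabilities.
#' @param truth binary matrix of the same shape.
#' @param threshold binarization threshold in (0, 1) (default 0.5).
#' @param fov optional binary field-of-view mask.
#' @return A \code{confusion_counts} list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(prob_map, truth, threshold = 0.5, fov = NULL) {
  if (!all(dim(prob_map) == dim(truth)))
    stop("confusion_counts: shapes differ")
  if (threshold <= 0 || threshold >= 1)
    stop("confusion_counts: threshold must be in (0, 1)")
  keep <- if (is.null(fov)) TRUE else fov > 0
  p <- prob_map[keep] >= threshold
  y <- truth[keep] > 0
  structure(list(TP = sum(p & y), TN = sum(!p & !y),
                 FP = sum(p & !y), FN = sum(!p & y)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  TN %d  FP %d  FN %d (n = %d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Summary metrics from confusion counts
#'
#' Accuracy, sensitivity (recall of the vessel class), specificity,
#' precision and F1. A ratio with zero denominator is reported as 0 and
#' flagged in \code{undefined}.
#'
#' @param counts a \code{\link{confusion_counts}} result.
#' @return A \code{metrics_report} list.
#' @export
summarize_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) stop("summarize_metrics: no evaluated pixels")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(counts$TP, counts$TP + counts$FN)
  spec <- ratio(counts$TN, counts$TN + counts$FP)
  prec <- ratio(counts$TP, counts$TP + counts$FP)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  vals <- c(acc = (counts$TP + counts$TN) / tot,
            sens = sens, spec = spec, prec = prec, f1 = f1)
  undefined <- names(vals)[is.na(vals)]
  vals[is.na(vals)] <- 0
  structure(c(as.list(vals),
              list(counts = counts, undefined = undefined)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Acc %.4f  Sens %.4f  Spec %.4f  Prec %.4f  F1 %.4f%s\n",
              x$acc, x$sens, x$spec, x$prec, x$f1,
              if (!is.null(x$auc)) sprintf("  AUC %.4f", x$auc) else ""))
  if (length(x$undefined))
    cat("undefined (0/0, reported as 0):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique probability values as thresholds, producing one ROC
#' point per threshold, and integrates with the trapezoidal rule. With this
#' construction tied probabilities receive the half-credit convention, so
#' the result equals the Mann-Whitney (all-pairs) estimate exactly.
#'
#' @param prob_map numeric matrix or vector of vessel probabilities.
#' @param truth binary labels, same shape.
#' @param fov optional field-of-view mask restricting evaluation.
#' @return List with \code{roc} (data.frame threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
roc_auc <- function(prob_map, truth, fov = NULL) {
  if (length(prob_map) != length(truth))
    stop("roc_auc: shapes differ")
  keep <- if (is.null(fov)) rep(TRUE, length(truth)) else as.vector(fov > 0)
  p <- as.vector(prob_map)[keep]
  y <- as.vector(truth)[keep] > 0
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0) stop("roc_auc: no positive (vessel) pixels in truth")
  if (nneg == 0) stop("roc_auc: no negative (background) pixels in truth")
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; ys <- y[ord]
  # one ROC point after each block of tied probabilities
  last <- cumsum(rle(ps)$lengths)
  tp <- cumsum(ys)[last]
  fp <- cumsum(!ys)[last]
  tpr <- c(0, tp / npos)
  fpr <- c(0, fp / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = c(Inf, ps[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Full evaluation of a probability map
#'
#' Confusion-based metrics at the given threshold plus ROC/AUC.
#'
#' @inheritParams confusion_counts
#' @return A \code{metrics_report} with \code{auc} and \code{roc} attached.
#' @export
evaluate_map <- function(prob_map, truth, threshold = 0.5, fov = NULL) {
  rep <- summarize_metrics(confusion_counts(prob_map, truth, threshold, fov))
  ra <- roc_auc(prob_map, truth, fov)
  rep$auc <- ra$auc
  rep$roc <- ra$roc
  rep$threshold <- threshold
  rep$fov_restricted <- !is.null(fov)
  rep
}
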