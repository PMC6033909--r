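#' Confusion matrix over a fixed class set
#'
#' @param true,predicted vectors of class labels.
#' @param classes ordered class names; defaults to the sorted union.
#' @return An m x m integer matrix, rows = true class, cols = predicted.
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(as.character(true),
                                                 as.character(predicted))))
  table(factor(as.character(true), levels = classes),
        factor(as.character(predicted), levels = classes),
        dnn = c("true", "predicted"))
}

#' Binary Matthews correlation coefficient
#'
#' Correlation between observed and predicted binary classifications:
#' 1 for perfect prediction, 0 for chance, -1 for total disagreement.
#' When any marginal of the confusion matrix is zero the denominator
#' degenerates and 0 is returned.
#'
#' @param confusion a 2 x 2 count matrix, rows = true, cols = predicted.
#' @return A number in \[-1, 1\].
#' @export
mcc_binary <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == 2L))
  if (any(confusion < 0)) stop("negative counts")
  if (sum(confusion) == 0) stop("empty confusion matrix")
  tp <- confusion[1, 1]; fn <- confusion[1, 2]
  fp <- confusion[2, 1]; tn <- confusion[2, 2]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Multi-class Matthews correlation coefficient
#'
#' The R_K generalization computed from the full m x m confusion
#' matrix; for m = 2 it coincides with [mcc_binary()]. With total
#' count s, trace c, per-class true counts t_k and predicted counts
#' p_k:
#' \deqn{MCC = \frac{c\,s - \sum_k p_k t_k}
#'   {\sqrt{s^2 - \sum_k p_k^2}\,\sqrt{s^2 - \sum_k t_k^2}}}
#' Degenerate denominators (all mass in one row or column) return 0.
#'
#' @param confusion an m x m count matrix, rows = true, cols = predicted.
#' @return A number in \[-1, 1\].
#' @export
mcc_multiclass <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!length(confusion) || nrow(confusion) != ncol(confusion) ||
      nrow(confusion) < 2L)
    stop("confusion must be a square matrix with m >= 2")
  if (any(confusion < 0)) stop("negative counts")
  s <- sum(confusion)
  if (s == 0) stop("empty confusion matrix")
  cc <- sum(diag(confusion))
  tk <- rowSums(confusion)
  pk <- colSums(confusion)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  (cc * s - sum(pk * tk)) / den
}

# Per-class one-vs-rest metrics from a pooled confusion matrix.
per_class_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  classes <- rownames(confusion)
  out <- data.frame(class = classes, precision = NA_real_, recall = NA_real_,
                    mcc = NA_real_, f = NA_real_, stringsAsFactors = FALSE)
  s <- sum(confusion)
  for (i in seq_along(classes)) {
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    tn <- s - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    out$precision[i] <- prec
    out$recall[i] <- rec
    out$mcc[i] <- mcc_binary(matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE))
    out$f[i] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  out
}

macro_f <- function(confusion) mean(per_class_metrics(confusion)$f)
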