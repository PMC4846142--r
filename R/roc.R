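#' Receiver operating characteristic curve and AUC
#'
#' Builds the ROC curve by sweeping a threshold over the distinct
#' prediction scores (predicting diseased when score >= threshold) and
#' integrates the area under the curve by the trapezoidal rule, so that
#' tied scores contribute half weight — the curve's area equals the
#' concordant-pair (Mann-Whitney) statistic.
#'
#' For an [ann_ensemble()] the scores are the pooled cross-validation
#' predictions (each record averaged over the models that held it out)
#' and `auc_se` is the standard deviation of the per-model held-out AUCs
#' across the ensemble.
#'
#' @param x prediction scores (higher = more diseased), or an
#'   `ann_ensemble`.
#' @param ... passed to methods.
#' @return Object of class `roc_curve`: `thresholds`, `fpr`, `tpr`,
#'   `auc`, and `auc_se` (NA unless computed from an ensemble).
#' @export
roc_curve <- function(x, ...) UseMethod("roc_curve")

#' @rdname roc_curve
#' @param labels binary vector (0/1, logical, or healthy/diseased factor);
#'   1/diseased is the positive class.
#' @export
roc_curve.default <- function(x, labels, ...) {
  scores <- as.numeric(x)
  if (is.factor(labels)) labels <- labels == "diseased"
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: labels contain a single class")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr,
                 auc = auc, auc_se = NA_real_),
            class = "roc_curve")
}

#' @rdname roc_curve
#' @export
roc_curve.ann_ensemble <- function(x, ...) {
  if (x$target != "status")
    stop("ROC requires a binary status target")
  labels <- as.integer(x$y)
  roc <- roc_curve(x$pooled_cv, labels)
  per_model <- vapply(seq_len(x$n_models), function(m) {
    held <- !is.na(x$cv_pred[, m])
    if (length(unique(labels[held])) < 2) return(NA_real_)
    roc_curve(x$cv_pred[held, m], labels[held])$auc
  }, numeric(1))
  roc$auc_se <- stats::sd(per_model, na.rm = TRUE)
  roc$per_model_auc <- per_model
  roc
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f", x$auc))
  if (!is.na(x$auc_se)) cat(sprintf(" (ensemble SD %.3f)", x$auc_se))
  cat(sprintf("; %d thresholds\n", length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l",
                 xlab = "false positive rate",
                 ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Export a ROC curve as a data frame
#'
#' @param x a `roc_curve`.
#' @param row.names,optional,... standard [as.data.frame()] arguments,
#'   ignored.
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
as.data.frame.roc_curve <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
}
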