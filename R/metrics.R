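#' Confusion counts
#'
#' Bundle of true/false positive/negative counts from which every
#' threshold-based metric is derived.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (sum(counts) == 0)
    stop("confusion counts sum to zero")
  structure(as.list(counts), class = "confusion_counts")
}

#' Tabulate confusion counts from predictions and labels
#'
#' @param predicted,actual Logical (or 0/1) vectors; `TRUE`/1 is the
#'   positive class.
#' @return A `confusion_counts` object.
#' @export
tabulate_confusion <- function(predicted, actual) {
  predicted <- as.logical(predicted); actual <- as.logical(actual)
  stopifnot(length(predicted) == length(actual))
  confusion_counts(tp = sum(predicted & actual),
                   tn = sum(!predicted & !actual),
                   fp = sum(predicted & !actual),
                   fn = sum(!predicted & actual))
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Threshold-based evaluation metrics
#'
#' Computes accuracy, precision, recall (TPR), TNR, F1, the Matthews
#' correlation coefficient and the balanced-accuracy AUC, (TPR + TNR) / 2,
#' from confusion counts. Undefined ratios (zero denominator) are reported
#' as `NA` and listed in the `undefined` field rather than coerced to 0.
#'
#' Two quantities are deliberately kept distinct throughout the package:
#' `auc_balanced` is the threshold-based (TPR + TNR) / 2 summary, while
#' ranking AUC from continuous scores is computed by [roc_auc()]. They
#' coincide only in special cases.
#'
#' @param counts A `confusion_counts` object.
#' @return A named list of class `eval_report` with fields `accuracy`,
#'   `precision`, `recall`, `tnr`, `f1`, `mcc`, `auc_balanced`, `counts`,
#'   and `undefined` (character vector naming NA metrics).
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  accuracy  <- safe_ratio(tp + tn, tp + tn + fp + fn)
  precision <- safe_ratio(tp, tp + fp)
  recall    <- safe_ratio(tp, tp + fn)
  tnr       <- safe_ratio(tn, tn + fp)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else
    (tp * tn - fp * fn) / sqrt(mcc_den)
  auc_balanced <- if (is.na(recall) || is.na(tnr)) NA_real_ else
    (recall + tnr) / 2
  out <- list(accuracy = accuracy, precision = precision, recall = recall,
              tnr = tnr, f1 = f1, mcc = mcc, auc_balanced = auc_balanced,
              counts = counts)
  out$undefined <- names(which(vapply(
    out[c("accuracy", "precision", "recall", "tnr", "f1", "mcc",
          "auc_balanced")], is.na, logical(1))))
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report\n")
  for (m in c("accuracy", "precision", "recall", "tnr", "f1", "mcc",
              "auc_balanced")) {
    v <- x[[m]]
    cat(sprintf("  %-12s %s\n", m, if (is.na(v)) "undefined"
                else formatC(v, digits = 4, format = "f")))
  }
  if ("auc_roc" %in% names(x) && !is.null(x$auc_roc))
    cat(sprintf("  %-12s %s\n", "auc_roc", formatC(x$auc_roc, digits = 4,
                                                   format = "f")))
  if ("aupr" %in% names(x) && !is.null(x$aupr))
    cat(sprintf("  %-12s %s\n", "aupr", formatC(x$aupr, digits = 4,
                                                format = "f")))
  cn <- x$counts
  cat(sprintf("  counts: TP=%d TN=%d FP=%d FN=%d\n", cn$tp, cn$tn, cn$fp,
              cn$fn))
  invisible(x)
}

check_scores_labels <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            !anyNA(labels))
  labels
}

#' Ranking ROC-AUC
#'
#' Area under the ROC curve via the Mann-Whitney rank statistic: the
#' probability that a random positive outscores a random negative, ties
#' counting one half.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Binary labels (`TRUE`/1 = positive).
#' @return AUC in `[0, 1]`, or `NA` (with a warning) if only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    warning("roc_auc undefined: single-class input")
    return(NA_real_)
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall curve and average precision
#'
#' Computes the precision-recall operating points at every distinct score
#' threshold and summarises them by average precision (the step-function
#' integral of precision over recall, no linear interpolation).
#'
#' @inheritParams roc_auc
#' @return A list with `curve` (data.frame: threshold, recall, precision)
#'   and `aupr` (average precision), or both `NA` with a warning when no
#'   positives exist.
#' @export
pr_curve <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  n_pos <- sum(labels)
  if (n_pos == 0) {
    warning("pr_curve undefined: no positive labels")
    return(list(curve = NULL, aupr = NA_real_))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y); cum_pred <- seq_along(y)
  # collapse tied scores to single thresholds (last index of each tie block)
  last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  rec <- cum_tp[last] / n_pos
  prec <- cum_tp[last] / cum_pred[last]
  ap <- sum(diff(c(0, rec)) * prec)
  list(curve = data.frame(threshold = s[last], recall = rec,
                          precision = prec),
       aupr = ap)
}

#' Binary cross-entropy loss
#'
#' `-1/(m+n) * (sum(log p+) + sum(log(1 - p-)))` with `m` positives scored
#' `pos_probs` and `n` negatives scored `neg_probs`; probabilities are
#' clipped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param pos_probs Predicted positive-class probabilities of the positive
#'   examples.
#' @param neg_probs Predicted positive-class probabilities of the negative
#'   examples.
#' @param eps Clipping guard, default `1e-7`.
#' @return The mean loss (a single non-negative number).
#' @export
cross_entropy_loss <- function(pos_probs, neg_probs, eps = 1e-7) {
  m <- length(pos_probs); n <- length(neg_probs)
  if (m + n == 0) stop("cross_entropy_loss: empty input")
  p <- pmin(pmax(pos_probs, eps), 1 - eps)
  q <- pmin(pmax(neg_probs, eps), 1 - eps)
  -(sum(log(p)) + sum(log(1 - q))) / (m + n)
}

#' Full score-based evaluation
#'
#' Thresholds scores at `threshold`, computes every confusion metric and
#' attaches the ranking metrics (ROC-AUC, AUPR).
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold on the score, default 0.5.
#' @return An `eval_report` with extra fields `auc_roc` and `aupr`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  labels <- check_scores_labels(scores, labels)
  rep <- confusion_metrics(tabulate_confusion(scores > threshold, labels))
  rep$auc_roc <- if (sum(labels) > 0 && sum(!labels) > 0)
    roc_auc(scores, labels) else NA_real_
  rep$aupr <- if (sum(labels) > 0) pr_curve(scores, labels)$aupr else
    NA_real_
  rep
}

#' Serialize evaluation reports as a flat metric table
#'
#' One row per report with identifying columns prepended, matching the
#' layout of a per-model performance table (target, algorithm, seed, split,
#' then all metrics).
#'
#' @param reports A list of `eval_report` objects.
#' @param info A data.frame with one row per report (e.g. target,
#'   algorithm, seed, split). Optional.
#' @return A data.frame.
#' @export
metric_table <- function(reports, info = NULL) {
  rows <- lapply(reports, function(r) {
    data.frame(accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, tnr = r$tnr, f1 = r$f1, mcc = r$mcc,
               auc_balanced = r$auc_balanced,
               auc_roc = if (is.null(r$auc_roc)) NA_real_ else r$auc_roc,
               aupr = if (is.null(r$aupr)) NA_real_ else r$aupr,
               tp = r$counts$tp, tn = r$counts$tn, fp = r$counts$fp,
               fn = r$counts$fn)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(info)) tab <- cbind(info, tab)
  rownames(tab) <- NULL
  tab
}
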