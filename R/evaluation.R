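#' Confusion matrix for a binary classifier
#'
#' Tallies true/false positives and negatives for predicted versus actual
#' class labels. The positive class (Parkinson's disease in this package's
#' pipelines) is named explicitly so the sensitivity/specificity convention
#' is unambiguous.
#'
#' @param labels Vector of actual classes.
#' @param predictions Vector of predicted classes, same length.
#' @param positive The label counted as positive (default `"PD"`; use `1`
#'   for 0/1 encoded labels).
#' @return Object of class `"confusion_matrix"`: list with integer counts
#'   `tp`, `tn`, `fp`, `fn` and the `positive` label.
#' @examples
#' confusion(c(1, 0, 1), c(1, 0, 1), positive = 1)
#' @export
confusion <- function(labels, predictions, positive = "PD") {
  if (length(labels) != length(predictions) || length(labels) == 0L) {
    stop("`labels` and `predictions` must be non-empty and equal length",
         call. = FALSE)
  }
  values <- unique(c(as.character(labels), as.character(predictions)))
  if (length(values) > 2L) {
    stop("inputs are not binary: found values ",
         paste(values, collapse = ", "), call. = FALSE)
  }
  actual_pos <- as.character(labels) == as.character(positive)
  pred_pos <- as.character(predictions) == as.character(positive)
  structure(list(
    tp = sum(actual_pos & pred_pos),
    tn = sum(!actual_pos & !pred_pos),
    fp = sum(!actual_pos & pred_pos),
    fn = sum(actual_pos & !pred_pos),
    positive = positive
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (positive = %s)\n", x$positive))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(actual = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(t(m))
  invisible(x)
}

#' Score metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity (recall) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and the F1 score
#' `2 * precision * recall / (precision + recall)`. A metric whose
#' denominator is zero is reported as 0 and named in the `degenerate`
#' field rather than raising, so batch evaluation always completes.
#'
#' @param cm A `"confusion_matrix"`.
#' @return Object of class `"metrics_report"`: the five metrics, the count
#'   echo, and `degenerate` (character vector of zero-denominator metrics).
#' @examples
#' cm_metrics(confusion(c(1, 1, 0, 0), c(1, 1, 0, 1), positive = 1))
#' @export
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  degenerate <- character()
  frac <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  sensitivity <- frac(cm$tp, cm$tp + cm$fn, "sensitivity")
  precision <- frac(cm$tp, cm$tp + cm$fp, "precision")
  structure(list(
    accuracy = (cm$tp + cm$tn) / total,
    sensitivity = sensitivity,
    specificity = frac(cm$tn, cm$tn + cm$fp, "specificity"),
    precision = precision,
    f1 = frac(2 * precision * sensitivity, precision + sensitivity, "f1"),
    counts = cm,
    degenerate = degenerate
  ), class = "metrics_report")
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over all distinct score
#' thresholds, which equals the probability that a random positive outranks
#' a random negative, with ties counted half (the Mann-Whitney statistic).
#'
#' @param scores Numeric classifier scores, higher meaning more positive.
#' @param labels Actual classes.
#' @param positive Label counted as positive.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(.9, .8, .3, .1), c(1, 1, 0, 0), positive = 1)  # 1
#' @export
roc_auc <- function(scores, labels, positive = "PD") {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  pos <- as.character(labels) == as.character(positive)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC is undefined: both classes must be present", call. = FALSE)
  }
  rc <- roc_curve(scores, pos)
  # trapezoid over the (FPR, TPR) polyline
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

# ROC polyline at every distinct threshold, from (0,0) to (1,1); tied
# scores collapse into a single vertex, which is what gives the
# ties-count-half trapezoid.
roc_curve <- function(scores, pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- c(s[-length(s)] != s[-1L], TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(p)[keep] / sum(p))
  fpr <- c(0, cumsum(!p)[keep] / sum(!p))
  list(fpr = fpr, tpr = tpr)
}

#' Full metrics report for scored predictions
#'
#' Thresholds sigmoid scores at `threshold` (default 0.5), builds the
#' confusion matrix, computes the five count metrics and the AUC from the
#' raw scores.
#'
#' @inheritParams roc_auc
#' @param threshold Score at or above which a record is called positive.
#' @return A `"metrics_report"` including `auc`.
#' @export
evaluate_scores <- function(scores, labels, positive = "PD",
                            threshold = 0.5) {
  neg <- setdiff(unique(as.character(labels)), as.character(positive))[1L]
  pred <- ifelse(scores >= threshold, as.character(positive), neg)
  rep <- cm_metrics(confusion(labels, pred, positive = positive))
  rep$auc <- roc_auc(scores, labels, positive = positive)
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Performance measures\n")
  rows <- c(Accuracy = x$accuracy, Sensitivity = x$sensitivity,
            Specificity = x$specificity, Precision = x$precision,
            `F1-Score` = x$f1)
  if (!is.null(x$auc)) rows <- c(rows, `AUC-ROC` = x$auc)
  for (nm in names(rows)) {
    cat(sprintf("  %-12s %6.2f%%\n", nm, 100 * rows[[nm]]))
  }
  if (length(x$degenerate)) {
    cat("  [zero-denominator, reported as 0:",
        paste(x$degenerate, collapse = ", "), "]\n")
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param x A `"metrics_report"`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
metrics_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "metrics_report"))
  obj <- list(accuracy = x$accuracy, sensitivity = x$sensitivity,
              specificity = x$specificity, precision = x$precision,
              f1 = x$f1, auc = x$auc,
              counts = list(tp = x$counts$tp, tn = x$counts$tn,
                            fp = x$counts$fp, fn = x$counts$fn),
              degenerate = x$degenerate)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
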