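#' Evaluate multiclass predictions (one-vs-rest)
#'
#' For each class k, the confusion matrix yields TP/FP/FN/TN against the
#' rest; per-class accuracy is (TP+TN)/n, precision TP/(TP+FP), recall
#' TP/(TP+FN), F1 their harmonic mean, and AUC the one-vs-rest ROC area of
#' the class's score column (trapezoidal, via pROC). Macro metrics are
#' unweighted means over classes. A class absent from `yTrue` has undefined
#' AUC; it is recorded as NA and excluded from the macro average with a
#' warning.
#'
#' @param yTrue,yPred character/factor vectors of equal length.
#' @param yScores optional n x K score matrix (rows summing to 1), columns
#'   ordered as `labels`; required for AUC.
#' @param labels class label set (default: union of observed labels).
#' @return a [MetricsReport-class]; all metrics stored as proportions.
#' @export
evaluateClassifier <- function(yTrue, yPred, yScores = NULL, labels = NULL) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  stopifnot(length(yTrue) == length(yPred))
  if (is.null(labels)) labels <- sort(unique(c(yTrue, yPred)))
  n <- length(yTrue)
  conf <- table(factor(yTrue, levels = labels), factor(yPred, levels = labels))
  conf <- matrix(as.integer(conf), length(labels), length(labels),
                 dimnames = list(truth = labels, prediction = labels))
  perClass <- data.frame(class = labels, accuracy = NA_real_,
                         precision = NA_real_, recall = NA_real_,
                         f1 = NA_real_, auc = NA_real_,
                         stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    tp <- conf[i, i]
    fn <- sum(conf[i, ]) - tp
    fp <- sum(conf[, i]) - tp
    tn <- n - tp - fn - fp
    perClass$accuracy[i] <- (tp + tn) / n
    perClass$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    perClass$recall[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    pr <- perClass$precision[i]; rc <- perClass$recall[i]
    perClass$f1[i] <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    if (!is.null(yScores)) {
      resp <- yTrue == labels[i]
      if (length(unique(resp)) == 2L) {
        perClass$auc[i] <- as.numeric(pROC::auc(
          response = resp, predictor = yScores[, i], quiet = TRUE,
          direction = "<", levels = c(FALSE, TRUE)))
      } else {
        warning("class '", labels[i],
                "' absent from truth (or the only class): AUC undefined, ",
                "excluded from the macro average")
      }
    }
  }
  macro <- c(accuracy = mean(perClass$accuracy),
             precision = mean(perClass$precision),
             recall = mean(perClass$recall),
             f1 = mean(perClass$f1),
             auc = if (all(is.na(perClass$auc))) NA_real_
                   else mean(perClass$auc, na.rm = TRUE))
  new("MetricsReport", confusion = conf, perClass = perClass, macro = macro,
      labels = labels, nTest = as.integer(n))
}

#' Overall (micro) accuracy of a report
#'
#' `trace(confusion) / n`.
#' @param report a [MetricsReport-class].
#' @return scalar proportion.
#' @export
microAccuracy <- function(report) {
  sum(diag(report@confusion)) / report@nTest
}
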