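#' @include AllGenerics.R utils.R
NULL

#' Build a multi-class confusion matrix
#'
#' @param truth True class per sample.
#' @param predicted Predicted class per sample.
#' @param levels Class levels; default the sorted union of both vectors.
#' @return A [ConfusionCounts-class] with true classes in rows.
#' @export
confusionCounts <- function(truth, predicted,
                            levels = sort(unique(c(truth, predicted)))) {
  stopifnot(length(truth) == length(predicted))
  m <- table(factor(as.character(truth), levels = levels),
             factor(as.character(predicted), levels = levels))
  m <- matrix(as.integer(m), nrow(m), ncol(m),
              dimnames = list(levels, levels))
  new("ConfusionCounts", counts = m)
}

#' @rdname countsMatrix
#' @export
setMethod("countsMatrix", "ConfusionCounts", function(x) x@counts)

#' @rdname ovrCounts
#' @export
setMethod("ovrCounts", "ConfusionCounts", function(x) {
  m <- x@counts
  total <- sum(m)
  data.frame(
    class = rownames(m),
    TP = diag(m),
    FP = colSums(m) - diag(m),
    FN = rowSums(m) - diag(m),
    TN = total - rowSums(m) - colSums(m) + diag(m),
    row.names = NULL)
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts (", sum(object@counts),
      " samples; rows = truth)\n", sep = "")
  print(object@counts)
})

# Zero denominators yield NA (an undefined metric), never 0.
.safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Per-class classification metrics
#'
#' Closed-form one-vs-rest metrics from TP/FP/TN/FN counts:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/(TP+FP+TN+FN), and the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)). A metric whose
#' denominator is zero is undefined and reported as `NA`, never as 0. All
#' functions are vectorized.
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return Numeric value(s); sensitivity/specificity/accuracy in [0,1],
#'   MCC in [-1,1].
#' @examples
#' sensitivity(90, 10)        # 0.9
#' mcc(50, 0, 50, 0)          # 1: perfect prediction
#' mcc(0, 50, 0, 50)          # -1: perfect anti-correlation
#' @name classMetrics
NULL

#' @rdname classMetrics
#' @export
sensitivity <- function(TP, FN) .safe_ratio(TP, TP + FN)

#' @rdname classMetrics
#' @export
specificity <- function(TN, FP) .safe_ratio(TN, TN + FP)

#' @rdname classMetrics
#' @export
accuracyRatio <- function(TP, FP, TN, FN)
  .safe_ratio(TP + TN, TP + FP + TN + FN)

#' @rdname classMetrics
#' @export
mcc <- function(TP, FP, TN, FN) {
  TP <- as.numeric(TP); FP <- as.numeric(FP)
  TN <- as.numeric(TN); FN <- as.numeric(FN)
  den <- sqrt((TP + FN) * (TP + FP) * (TN + FP) * (TN + FN))
  ifelse(den > 0, (TP * TN - FP * FN) / den, NA_real_)
}

#' ROC curve and AUC for one-vs-rest scores
#'
#' Computes the ROC curve over all score thresholds and its area by the
#' rank-based (Mann-Whitney) formulation, which counts tied scores as
#' half-concordant — identical to trapezoidal integration of the
#' tie-grouped curve.
#'
#' @param scores Numeric decision value per sample (larger = more
#'   positive).
#' @param truth Binary truth per sample: logical, 0/1, or a two-level
#'   vector whose larger level (or `positive`) is the positive class.
#' @param positive Optional value of `truth` marking positives.
#' @return List with `auc` and `curve`, a data.frame of (fpr, tpr) points
#'   from (0,0) to (1,1).
#' @examples
#' rocAuc(c(3, 2, 1, 0), c(1, 1, 0, 0))$auc  # 1: perfect separation
#' @export
rocAuc <- function(scores, truth, positive = NULL) {
  stopifnot(length(scores) == length(truth))
  if (is.null(positive)) {
    u <- sort(unique(as.character(truth)))
    if (length(u) != 2L)
      stop("truth must contain exactly two classes", call. = FALSE)
    positive <- u[2L]
  }
  pos <- as.character(truth) == as.character(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present in truth", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # tie-grouped curve, thresholds descending
  ord <- order(-scores)
  s <- scores[ord]; p <- pos[ord]
  keep <- c(diff(s) != 0, TRUE)        # last index of each tied block
  tpr <- cumsum(p)[keep] / n1
  fpr <- cumsum(!p)[keep] / n0
  list(auc = auc,
       curve = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Full metrics report from a confusion matrix
#'
#' Per-class one-vs-rest sensitivity, specificity and MCC, overall
#' accuracy (trace over total), macro averages, and — when one-vs-rest
#' decision scores are supplied — per-class and macro AUC.
#'
#' @param confusion A [ConfusionCounts-class].
#' @param scores Optional samples x classes decision-score matrix (e.g.
#'   from [crossValidate()] or [decisionScores()]).
#' @param truth Class labels matching `scores` rows (required with
#'   `scores`).
#' @return A [MetricsReport-class].
#' @export
metricsReport <- function(confusion, scores = NULL, truth = NULL) {
  stopifnot(is(confusion, "ConfusionCounts"))
  ovr <- ovrCounts(confusion)
  per <- data.frame(
    class = ovr$class,
    sensitivity = sensitivity(ovr$TP, ovr$FN),
    specificity = specificity(ovr$TN, ovr$FP),
    mcc = mcc(ovr$TP, ovr$FP, ovr$TN, ovr$FN))
  if (!is.null(scores)) {
    if (is.null(truth) || nrow(scores) != length(truth))
      stop("scores need a matching truth vector", call. = FALSE)
    per$auc <- vapply(per$class, function(cl) {
      tr <- as.character(truth) == cl
      if (!any(tr) || all(tr)) return(NA_real_)
      rocAuc(scores[, cl], tr, positive = "TRUE")$auc
    }, numeric(1))
  }
  m <- confusion@counts
  macro <- vapply(setdiff(names(per), "class"),
                  function(cn) mean(per[[cn]], na.rm = TRUE), numeric(1))
  new("MetricsReport", perClass = per,
      overallAccuracy = sum(diag(m)) / sum(m), macro = macro)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: overall accuracy %.2f%%\n",
              100 * object@overallAccuracy))
  df <- object@perClass
  out <- data.frame(class = df$class,
                    `sensitivity (%)` = round(100 * df$sensitivity, 2),
                    `specificity (%)` = round(100 * df$specificity, 2),
                    mcc = round(df$mcc, 3),
                    check.names = FALSE)
  if (!is.null(df$auc)) out$auc <- round(df$auc, 3)
  print(out, row.names = FALSE)
  cat("macro:", paste(sprintf("%s = %.3f", names(object@macro),
                              object@macro), collapse = ", "), "\n")
})

#' Serialize a metrics report to JSON
#'
#' @param x A [MetricsReport-class].
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
metricsReportJSON <- function(x, path = NULL) {
  stopifnot(is(x, "MetricsReport"))
  obj <- list(overall_accuracy = x@overallAccuracy,
              per_class = x@perClass,
              macro = as.list(x@macro))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows", na = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write ROC curve points to TSV
#'
#' @param roc Result of [rocAuc()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeRocPoints <- function(roc, path) {
  utils::write.table(roc$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
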