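METRIC_NAMES <- c("precision", "sensitivity", "specificity", "fdr",
                  "accuracy", "f_measure")

#' Confusion-matrix counts for binary predictions
#'
#' Tallies true/false positives/negatives of a prediction against the
#' actual class, with an explicit declaration of which label counts as
#' positive.
#'
#' @param yTrue,yPred label vectors of equal length; jointly at most two
#'   distinct labels.
#' @param positive the label treated as the positive class (default
#'   "positive").
#' @return named integer vector \code{c(TP, FP, TN, FN)}.
#' @examples
#' confusionCounts(c("positive", "negative"), c("positive", "positive"))
#' @export
confusionCounts <- function(yTrue, yPred, positive = "positive") {
    if (length(yTrue) != length(yPred))
        stop("yTrue and yPred must have equal length")
    labs <- unique(c(as.character(yTrue), as.character(yPred)))
    if (length(labs) > 2L)
        stop("labels must be binary; found: ", paste(labs, collapse = ", "))
    tp <- as.character(yTrue) == positive
    pp <- as.character(yPred) == positive
    c(TP = sum(tp & pp), FP = sum(!tp & pp),
      TN = sum(!tp & !pp), FN = sum(tp & !pp))
}

#' The six standard performance measures from a confusion matrix
#'
#' Precision TP/(TP+FP), sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' false discovery rate FP/(FP+TP), accuracy (TP+TN)/total, and F-measure
#' 2*Prec*Sens/(Prec+Sens), all on the percentage scale. A measure whose
#' denominator is zero is reported as \code{NA} (explicitly undefined) and
#' is never substituted by a number; cross-fold averaging drops undefined
#' values with a warning rather than coercing them.
#'
#' @param cm named counts \code{c(TP, FP, TN, FN)}, e.g. from
#'   \code{\link{confusionCounts}}.
#' @return named numeric vector of the six measures in percent (\code{NA}
#'   = undefined).
#' @examples
#' metricSet(c(TP = 3, FP = 1, TN = 4, FN = 2))
#' @export
metricSet <- function(cm) {
    need <- c("TP", "FP", "TN", "FN")
    if (!all(need %in% names(cm))) stop("cm needs counts TP, FP, TN, FN")
    tp <- cm[["TP"]]; fp <- cm[["FP"]]; tn <- cm[["TN"]]; fn <- cm[["FN"]]
    if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be nonnegative")
    total <- tp + fp + tn + fn
    if (total == 0) stop("empty confusion matrix (total = 0)")
    frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    prec <- frac(tp, tp + fp)
    sens <- frac(tp, tp + fn)
    spec <- frac(tn, tn + fp)
    fdr <- frac(fp, fp + tp)
    acc <- 100 * (tp + tn) / total
    f <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
        2 * prec * sens / (prec + sens) else NA_real_
    out <- c(prec, sens, spec, fdr, acc, f)
    names(out) <- METRIC_NAMES
    out
}

## Component-wise mean of per-fold metric sets; undefined (NA) folds are
## excluded per metric with a warning, never coerced to 0.
foldMeanMetrics <- function(perFold) {
    if (anyNA(perFold))
        warning("undefined metric value(s) excluded from the cross-fold mean",
                call. = FALSE)
    colMeans(perFold, na.rm = TRUE)
}

#' Write a per-fold metrics report
#'
#' One row per fold plus an "Average" row, with the six measures in
#' percent at two decimals.
#'
#' @param perFold numeric matrix, folds x 6 metrics (columns named as in
#'   \code{\link{metricSet}}).
#' @param file path or connection.
#' @return the report data.frame, invisibly.
#' @export
writeMetricsReport <- function(perFold, file) {
    avg <- foldMeanMetrics(perFold)
    df <- data.frame(Fold = c(seq_len(nrow(perFold)), "Average"),
                     rbind(perFold, avg), check.names = FALSE,
                     row.names = NULL)
    for (m in METRIC_NAMES) df[[m]] <- sprintf("%.2f", df[[m]])
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
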