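#' Confusion counts
#'
#' Tallies true/false positives/negatives of a binary prediction against
#' truth, with an explicit positive class.
#'
#' @param pred,truth equal-length label vectors.
#' @param positive the label counted as positive (default `"abnormal"`).
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusion(c(1, 1, 1, 0, 0), c(1, 0, 1, 0, 1), positive = 1)
#' @export
confusion <- function(pred, truth, positive = "abnormal") {
  if (length(pred) != length(truth)) stop("length mismatch", call. = FALSE)
  p <- as.character(pred) == as.character(positive)
  t <- as.character(truth) == as.character(positive)
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

.safe_ratio <- function(num, den, name) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reporting NaN", name),
            call. = FALSE)
    return(NaN)
  }
  num / den
}

#' Confusion-matrix metric report
#'
#' Computes the standard suite from TP/TN/FP/FN counts: accuracy,
#' sensitivity (recall), specificity, precision, false positive rate, false
#' negative rate, negative predictive value, false discovery rate, F1 score
#' and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Metrics with a zero denominator are reported as `NaN` with a warning.
#' The complement identities `FPR = 1 - specificity`,
#' `FNR = 1 - sensitivity` and `FDR = 1 - precision` hold to working
#' precision whenever defined.
#'
#' @param counts a [confusion()] result (or list with TP/TN/FP/FN).
#' @return one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `fpr`, `fnr`, `npv`, `fdr`, `f1`, `mcc`.
#' @examples
#' metric_report(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0), positive = 1))
#' @export
metric_report <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  total <- TP + TN + FP + FN
  sens <- .safe_ratio(TP, TP + FN, "sensitivity")
  spec <- .safe_ratio(TN, TN + FP, "specificity")
  prec <- .safe_ratio(TP, TP + FP, "precision")
  f1 <- if (is.finite(prec) && is.finite(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NaN
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) {
    warning("mcc undefined (zero denominator); reporting NaN", call. = FALSE)
    NaN
  } else (TP * TN - FP * FN) / mcc_den
  tibble::tibble(
    accuracy = .safe_ratio(TP + TN, total, "accuracy"),
    sensitivity = sens,
    specificity = spec,
    precision = prec,
    fpr = .safe_ratio(FP, FP + TN, "fpr"),
    fnr = .safe_ratio(FN, FN + TP, "fnr"),
    npv = .safe_ratio(TN, TN + FN, "npv"),
    fdr = .safe_ratio(FP, TP + FP, "fdr"),
    f1 = f1,
    mcc = mcc
  )
}

#' One-vs-rest macro-averaged metrics for multi-class labels
#'
#' Reduces multi-class predictions to one binary report per class (that class
#' vs the rest) and macro-averages the metric columns.
#'
#' @param pred,truth label vectors.
#' @return tibble with one row per class plus a `"macro"` row; first column
#'   `class`.
#' @export
macro_metric_report <- function(pred, truth) {
  classes <- sort(unique(as.character(truth)))
  rows <- lapply(classes, function(cl) {
    tibble::add_column(metric_report(confusion(pred, truth, positive = cl)),
                       class = cl, .before = 1)
  })
  per <- do.call(rbind, rows)
  macro <- per[1, ]
  macro$class <- "macro"
  for (cn in setdiff(names(per), "class")) macro[[cn]] <- mean(per[[cn]])
  rbind(per, macro)
}
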