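#' Confusion matrix from binary label vectors
#'
#' Counts true/false positives and negatives for a binary classification
#' task.  The positive class (hERG inhibitor) is coded `1`, the negative
#' class (inactive) `0`.
#'
#' @param truth Vector of observed labels, each 0 or 1 (logicals accepted).
#' @param pred Vector of predicted labels, same length and coding.
#' @return An object of class `confusion_matrix`: a list with integer
#'   components `tp`, `fn`, `fp`, `tn`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop_data("truth and predicted label vectors differ in length (",
              length(truth), " vs ", length(pred), ")")
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  if (anyNA(truth) || anyNA(pred) ||
      !all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1)))
    stop_data("labels must be binary 0/1 with no missing values")
  cm <- list(tp = sum(truth == 1 & pred == 1),
             fn = sum(truth == 1 & pred == 0),
             fp = sum(truth == 0 & pred == 1),
             tn = sum(truth == 0 & pred == 0))
  cm <- lapply(cm, as.integer)
  structure(cm, class = "confusion_matrix")
}

#' Construct a confusion matrix from four counts
#'
#' Convenience constructor for recomputing published tables directly from
#' printed TP/FN/FP/TN counts.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(v) || any(v < 0) || any(v != floor(v)))
    stop_data("confusion counts must be non-negative integers")
  if (sum(v) == 0) stop_data("confusion matrix total must be positive")
  structure(lapply(as.list(v), as.integer), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (n = %d)\n", x$tp + x$fn + x$fp + x$tn))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("truth 1", "truth 0"),
                              c("pred 1", "pred 0")))
  m[2, ] <- c(x$fp, x$tn)
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification statistics from a confusion matrix
#'
#' Computes accuracy, sensitivity, specificity, balanced accuracy,
#' precision, and Cohen's kappa.  Kappa is the chance-corrected agreement
#' \eqn{(Po - Pe) / (1 - Pe)} where \eqn{Po} is the observed agreement
#' (= accuracy) and \eqn{Pe = [(TP+FN)(TP+FP) + (TN+FP)(TN+FN)] / N^2} is
#' the agreement expected by chance.  Any ratio with a zero denominator is
#' reported as `NA`, never silently 0; in particular kappa is `NA` when
#' `Pe == 1` (all mass in one cell).
#'
#' @param cm A `confusion_matrix`.
#' @return A `metric_set`: list with `accuracy`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `precision`, `po`, `pe`, `kappa`.
#' @examples
#' classification_metrics(confusion_matrix(996, 176, 147, 1041))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$tp); fn <- as.numeric(cm$fn)
  fp <- as.numeric(cm$fp); tn <- as.numeric(cm$tn)
  n <- tp + fn + fp + tn
  if (n == 0) stop_data("empty confusion matrix")
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  structure(list(
    accuracy = po,
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_
                        else (sens + spec) / 2,
    precision = safe_ratio(tp, tp + fp),
    po = po, pe = pe, kappa = kappa
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  v <- unlist(x[c("accuracy", "sensitivity", "specificity",
                  "balanced_accuracy", "precision", "kappa")])
  print(round_half_up(v, digits))
  invisible(x)
}

#' @export
format.metric_set <- function(x, digits = 3, ...) {
  v <- unlist(x[c("accuracy", "sensitivity", "specificity",
                  "balanced_accuracy", "precision", "kappa")])
  paste(names(v), sprintf(paste0("%.", digits, "f"),
                          round_half_up(v, digits)), sep = "=",
        collapse = " ")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs where the positive scores higher, ties
#' counting one half.  Equivalent to the trapezoidal area under the ROC
#' curve.
#'
#' @param scores Numeric prediction scores (larger = more positive).
#' @param truth Binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop_data("scores and truth differ in length")
  truth <- as.numeric(truth)
  if (!all(truth %in% c(0, 1))) stop_data("truth must be binary 0/1")
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0)
    stop_data("ROC AUC needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}
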