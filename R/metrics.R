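#' Confusion counts for the two extreme cognitive classes
#'
#' Tabulates true/false positives and negatives with `"PositiveAger"` as the
#' positive class and `"CognitiveDecliner"` as the negative class: `tp` counts
#' Positive-Agers predicted Positive-Ager, `fp` Cognitive Decliners predicted
#' Positive-Ager, `tn` Cognitive Decliners predicted Cognitive Decliner and
#' `fn` Positive-Agers predicted Cognitive Decliner.
#'
#' @param y_true,y_pred Vectors of class labels (character or factor) of equal
#'   length, each taking the two extreme-class values.
#' @param positive Label treated as the positive class.
#' @return A list of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion_counts(c("PositiveAger", "CognitiveDecliner"),
#'                  c("PositiveAger", "PositiveAger"))
confusion_counts <- function(y_true, y_pred, positive = "PositiveAger") {
  if (length(y_true) != length(y_pred))
    stop_opticog("y_true and y_pred must have equal length", "opticog_data_error")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  p_t <- y_true == positive
  p_p <- y_pred == positive
  out <- list(tp = sum(p_t & p_p), fp = sum(!p_t & p_p),
              tn = sum(!p_t & !p_p), fn = sum(p_t & !p_p))
  structure(out, class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 score. A
#' metric with a zero denominator is reported as `NA` with a warning, never
#' silently as 0.
#'
#' @param counts A `confusion_counts` object (or list with `tp`,`fp`,`tn`,`fn`).
#' @return Named list with `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what), call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    warning("f1 undefined", call. = FALSE)
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(accuracy = safe(tp + tn, tp + tn + fp + fn, "accuracy"),
       precision = precision, recall = recall,
       specificity = safe(tn, tn + fp, "specificity"), f1 = f1)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, with ties credited one half.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param y_true Binary ground truth: logical, 0/1, or labels equal to
#'   `positive`.
#' @param positive Value of `y_true` counted as positive when `y_true` is not
#'   already logical/0-1.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
auc <- function(scores, y_true, positive = "PositiveAger") {
  if (is.logical(y_true)) pos <- y_true
  else if (is.numeric(y_true)) pos <- y_true == 1
  else pos <- as.character(y_true) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_opticog("AUC undefined: only one class present", "opticog_data_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hedge's g effect size
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' small-sample correction factor `J = 1 - 3 / (4 * (na + nb) - 9)`. The
#' pooled standard deviation uses (n - 1) weights. Group order fixes the
#' sign: `hedges_g(a, b) == -hedges_g(b, a)`.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @return Signed effect size; `NA` (with warning) when the pooled variance
#'   is zero.
#' @export
hedges_g <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2)
    stop_opticog("each group needs >= 2 values", "opticog_data_error")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) {
    if (mean(group_a) == mean(group_b)) return(0)
    warning("Hedge's g undefined: zero pooled variance", call. = FALSE)
    return(NA_real_)
  }
  j <- 1 - 3 / (4 * (na + nb) - 9)
  j * (mean(group_a) - mean(group_b)) / sqrt(sp2)
}
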