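#' Unweighted (macro) F1 score
#'
#' Arithmetic mean of the per-class F1 scores over the two classes. A class
#' with zero predicted and zero true positives contributes F1 = 0. Robust to
#' class imbalance, which is why the leaderboards rank by it.
#'
#' @param y_true,y_pred Equal-length binary vectors over \{0, 1\}.
#' @return Macro F1 in [0, 1].
#' @export
macro_f1 <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be non-empty and of equal length")
  f1s <- vapply(c(0, 1), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  mean(f1s)
}

#' Classification accuracy
#' @inheritParams macro_f1
#' @return Fraction of agreeing labels.
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be non-empty and of equal length")
  mean(y_true == y_pred)
}

#' Binary confusion matrix
#'
#' @inheritParams macro_f1
#' @return 2x2 integer matrix `[TN, FP; FN, TP]` with dimnames
#'   `true` x `predicted` over classes 0/1; row sums equal class counts.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  m <- matrix(0L, 2L, 2L, dimnames = list(true = c("0", "1"),
                                          predicted = c("0", "1")))
  for (tcl in 0:1) for (pcl in 0:1)
    m[tcl + 1L, pcl + 1L] <- sum(y_true == tcl & y_pred == pcl)
  m
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, used to compare model-score sets between
#' representations. When both samples have zero variance and equal means the
#' comparison is defined as t = 0, p = 1.
#'
#' @param a,b Numeric score vectors (each of length >= 2).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2, p_value = 1))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
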