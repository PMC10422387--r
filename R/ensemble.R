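#' Average member probability matrices
#'
#' Elementwise arithmetic mean of the members' per-class probability
#' matrices (equal weights). Since each member's rows sum to 1, so do the
#' averaged rows.
#'
#' @param members List of numeric matrices of identical shape, rows
#'   summing to 1.
#' @return Matrix of the common shape.
#' @export
ensemble_average <- function(members) {
  if (!length(members)) err_validation("need at least one member")
  dims <- lapply(members, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    err_validation("member probability matrices differ in shape")
  }
  Reduce(`+`, members) / length(members)
}

#' Hard labels from a probability matrix
#'
#' Argmax per row; ties resolve to the lowest class code so predictions are
#' deterministic.
#'
#' @param probs Probability matrix, columns ordered by class code.
#' @return Integer class codes in `0..C-1`.
#' @export
predict_label <- function(probs) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  max.col(probs, ties.method = "first") - 1L
}

#' Confusion counts with respect to a positive class
#'
#' @param y_true,y_pred Integer class-code vectors of equal length.
#' @param positive Class code counted as positive.
#' @return Object of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred)) {
    err_validation("y_true and y_pred differ in length")
  }
  pt <- y_true == positive
  pp <- y_pred == positive
  structure(list(tp = sum(pt & pp), fp = sum(!pt & pp),
                 fn = sum(pt & !pp), tn = sum(!pt & !pp)),
            class = "confusion_counts")
}

#' Precision, recall, accuracy and F-measure from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/total`, and the F-measure is the harmonic mean
#' `2PR/(P+R)`. A zero denominator yields 0 with a warning (a degenerate
#' prediction pattern, e.g. no positive predictions at all).
#'
#' @param cc A `confusion_counts` object.
#' @return List with `precision`, `recall`, `accuracy`, `f_measure`.
#' @export
classification_metrics <- function(cc) {
  total <- cc$tp + cc$fp + cc$fn + cc$tn
  if (total == 0) err_validation("no evaluated instances")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as 0", what))
      0
    } else num / den
  }
  p <- safe_div(cc$tp, cc$tp + cc$fp, "precision")
  r <- safe_div(cc$tp, cc$tp + cc$fn, "recall")
  f <- if (p + r > 0) 2 * p * r / (p + r) else {
    warning("f-measure undefined (precision + recall = 0); reported as 0")
    0
  }
  list(precision = p, recall = r,
       accuracy = (cc$tp + cc$tn) / total, f_measure = f)
}

# Macro-averaged metrics over classes (one-vs-rest), used when C > 2.
macro_metrics <- function(y_true, y_pred, C) {
  per <- lapply(seq_len(C) - 1L, function(c) {
    suppressWarnings(classification_metrics(confusion_counts(y_true, y_pred, c)))
  })
  list(precision = mean(vapply(per, `[[`, numeric(1), "precision")),
       recall = mean(vapply(per, `[[`, numeric(1), "recall")),
       accuracy = mean(y_true == y_pred),
       f_measure = mean(vapply(per, `[[`, numeric(1), "f_measure")))
}
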