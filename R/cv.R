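#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the data into stratified folds and, within each training fold,
#' refits every stage from scratch: ADASYN, min-max parameters, feature
#' selection, and the three members. The held-out fold is only
#' min-max-transformed and mask-restricted — synthetic samples never enter
#' evaluation. Metrics are computed per fold against the minority class of
#' the full dataset (macro-averaged when there are more than two classes)
#' and averaged over folds.
#'
#' @param ds A [labeled_dataset].
#' @param folds Fold count (default 10). Reduced with a warning when the
#'   minority class has fewer instances than folds.
#' @param seed RNG seed; the whole protocol is deterministic given the seed.
#' @param ... Passed to [asdmlc()] (e.g. `select = FALSE` for the
#'   no-selection ablation arm).
#' @return Object of class `asdmlc_cv`: `per_fold` data frame (fold, n,
#'   precision, recall, accuracy, f_measure), `mean` of the four metrics,
#'   `folds`, `seed`, and the per-fold selected-feature masks.
#' @export
asdmlc_cv <- function(ds, folds = 10, seed = 1, ...) {
  cc <- class_counts(ds)
  if (cc$ms < folds) {
    folds <- max(2L, cc$ms)
    warning(sprintf("minority class smaller than fold count; using %d folds",
                    folds))
  }
  C <- n_classes(ds)
  fold <- stratified_folds(ds$y, folds, seed = seed)
  rows <- vector("list", folds)
  masks <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    dtr <- labeled_dataset(ds$x[tr, , drop = FALSE], ds$y[tr],
                           feature_names = ds$feature_names,
                           class_names = ds$class_names,
                           positive_class = ds$positive_class)
    fit <- asdmlc(dtr, seed = seed + f * 101L, ...)
    masks[[f]] <- fit$mask
    yhat <- predict(fit, ds$x[!tr, , drop = FALSE], type = "class")
    ytru <- ds$y[!tr]
    met <- if (C == 2L) {
      suppressWarnings(classification_metrics(
        confusion_counts(ytru, yhat, ds$positive_class)))
    } else {
      macro_metrics(ytru, yhat, C)
    }
    rows[[f]] <- data.frame(fold = f, n = sum(!tr),
                            precision = met$precision, recall = met$recall,
                            accuracy = met$accuracy,
                            f_measure = met$f_measure)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[c("precision", "recall", "accuracy", "f_measure")]),
    folds = folds, seed = seed, masks = masks),
    class = "asdmlc_cv")
}

#' @export
print.asdmlc_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold stratified cross-validation (seed %d)\n",
              x$folds, x$seed))
  cat(sprintf("  Accuracy:  %.*f\n  Precision: %.*f\n  Recall:    %.*f\n  F-measure: %.*f\n",
              digits, x$mean[["accuracy"]], digits, x$mean[["precision"]],
              digits, x$mean[["recall"]], digits, x$mean[["f_measure"]]))
  invisible(x)
}

#' With/without feature-selection ablation
#'
#' Runs the cross-validated pipeline twice per seed — once with VPSO
#' feature selection and once without — and tabulates the mean metrics side
#' by side, the standard way the contribution of a wrapper selector is
#' reported.
#'
#' @param ds A [labeled_dataset].
#' @param folds Fold count (default 10).
#' @param seeds Integer vector of seeds to average over (default 1).
#' @param ... Passed to [asdmlc_cv()] / [asdmlc()].
#' @return Object of class `asdmlc_ablation`: a `table` data frame (metric
#'   x arm, in percent) and the per-seed `runs`.
#' @export
asdmlc_ablate <- function(ds, folds = 10, seeds = 1L, ...) {
  runs <- lapply(seeds, function(s) {
    list(with = asdmlc_cv(ds, folds = folds, seed = s, select = TRUE, ...),
         without = asdmlc_cv(ds, folds = folds, seed = s, select = FALSE, ...))
  })
  mean_of <- function(arm, metric) {
    mean(vapply(runs, function(r) r[[arm]]$mean[[metric]], numeric(1)))
  }
  metrics <- c("accuracy", "precision", "recall", "f_measure")
  tab <- data.frame(
    metric = metrics,
    without_vpso = vapply(metrics, function(m) 100 * mean_of("without", m),
                          numeric(1)),
    with_vpso = vapply(metrics, function(m) 100 * mean_of("with", m),
                       numeric(1)),
    row.names = NULL)
  structure(list(table = tab, runs = runs, seeds = seeds),
            class = "asdmlc_ablation")
}

#' @export
print.asdmlc_ablation <- function(x, ...) {
  cat(sprintf("Ablation over %d seed(s), %% scale\n", length(x$seeds)))
  tab <- x$table
  tab$without_vpso <- sprintf("%.2f", tab$without_vpso)
  tab$with_vpso <- sprintf("%.2f", tab$with_vpso)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Multi-label evaluation by one-vs-rest binarization
#'
#' For a logical label matrix (instances x labels), runs the binary
#' cross-validated pipeline independently per label (each label against its
#' complement, thresholded at probability 0.5 via the argmax rule) and
#' macro-averages the per-label mean metrics.
#'
#' @param x Numeric feature matrix.
#' @param labels Logical or 0/1 matrix, one column per label; every label
#'   must have both positive and negative instances.
#' @param folds,seed As in [asdmlc_cv()].
#' @param ... Passed to [asdmlc()].
#' @return List with `per_label` (data frame of per-label mean metrics) and
#'   `macro` (their means).
#' @export
asdmlc_cv_multilabel <- function(x, labels, folds = 10, seed = 1, ...) {
  labels <- as.matrix(labels) != 0
  if (nrow(labels) != nrow(x)) err_validation("labels and features differ in rows")
  per <- lapply(seq_len(ncol(labels)), function(l) {
    y <- as.integer(labels[, l])
    if (length(unique(y)) < 2L) {
      err_validation(sprintf("label %d has a single class", l))
    }
    cv <- asdmlc_cv(labeled_dataset(x, y), folds = folds, seed = seed, ...)
    data.frame(label = colnames(labels)[l] %||% paste0("label", l),
               t(cv$mean))
  })
  per_label <- do.call(rbind, per)
  list(per_label = per_label,
       macro = colMeans(per_label[, -1L, drop = FALSE]))
}
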