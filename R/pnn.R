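#' Fit a probabilistic neural network
#'
#' A Parzen-window classifier: every training point is stored as the centre
#' of a Gaussian kernel, grouped by class. There is no optimization; the
#' class-conditional density estimate for a query is the average kernel
#' response over that class's centres, weighted by the class prior.
#'
#' @param ds Normalized [labeled_dataset]; every class must have at least
#'   one instance.
#' @param sigma Kernel spread, `> 0` (default 0.1, calibrated to
#'   \[0, 1\]-normalized features).
#' @return Object of class `pnn`.
#' @export
fit_pnn <- function(ds, sigma = 0.1) {
  if (sigma <= 0) err_config("sigma must be > 0")
  C <- n_classes(ds)
  tab <- tabulate(ds$y + 1L, nbins = C)
  if (any(tab == 0L)) {
    err_validation(sprintf("class '%s' has no training points",
                           ds$class_names[which(tab == 0L)[1]]))
  }
  structure(list(x = ds$x, y = ds$y, sigma = sigma,
                 priors = tab / sum(tab), class_names = ds$class_names,
                 positive_class = ds$positive_class),
            class = "pnn")
}

#' Predict class probabilities with a PNN
#'
#' The score for class c is
#' `prior_c * mean over class-c centres of exp(-||x - centre||^2 / (2 sigma^2))`,
#' normalized across classes. Scores are computed in log space, so as
#' `sigma -> 0` the prediction degrades gracefully to the nearest
#' neighbour's class rather than underflowing to the priors.
#'
#' @param object A `pnn` model.
#' @param newdata Numeric matrix with the training columns.
#' @param type `"prob"` (default) for a row-stochastic probability matrix,
#'   `"class"` for integer class codes.
#' @param ... Unused.
#' @export
predict.pnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$x
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != ncol(object$x)) {
    err_validation(sprintf("expected %d columns, got %d",
                           ncol(object$x), ncol(newdata)))
  }
  C <- length(object$class_names)
  d2 <- cross_sqdist(newdata, object$x)
  logscore <- matrix(NA_real_, nrow(newdata), C)
  for (c in seq_len(C) - 1L) {
    cols <- object$y == c
    k <- -d2[, cols, drop = FALSE] / (2 * object$sigma^2)
    logscore[, c + 1L] <- log(object$priors[c + 1L]) - log(sum(cols)) +
      row_logsumexp(k)
  }
  # softmax across classes (max-subtracted); ties cannot all be -Inf since
  # every class has >= 1 centre at finite distance
  mx <- apply(logscore, 1L, max)
  p <- exp(logscore - mx)
  p <- p / rowSums(p)
  colnames(p) <- object$class_names
  if (type == "class") predict_label(p) else p
}
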