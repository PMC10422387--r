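#' Fit min-max normalization parameters
#'
#' Records the exact columnwise extrema of the training features. The
#' transform maps each feature affinely so training extrema land on `low`
#' and `high` (defaults 0 and 1). Parameters are learned on training data
#' only and re-applied verbatim at prediction time.
#'
#' @param x A [labeled_dataset] or numeric matrix.
#' @param low,high Target range bounds, `high > low` (defaults 0, 1; use
#'   `low = -1` for a \[-1, 1\] range).
#' @return Object of class `minmax_params` with fields `min`, `max`, `low`,
#'   `high`. Constant columns are reported with a warning; they map to `low`.
#' @export
fit_minmax <- function(x, low = 0, high = 1) {
  if (inherits(x, "labeled_dataset")) x <- x$x
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 1L) err_validation("cannot fit normalization on empty data")
  if (high <= low) err_config("high must exceed low")
  mn <- apply(x, 2L, min)
  mx <- apply(x, 2L, max)
  const <- which(mx == mn)
  if (length(const)) {
    warning(sprintf("constant feature(s) map to low: %s",
                    paste(colnames(x)[const] %||% const, collapse = ", ")))
  }
  structure(list(min = mn, max = mx, low = low, high = high,
                 feature_names = colnames(x)),
            class = "minmax_params")
}

#' Apply min-max normalization
#'
#' `x_norm = (high - low) * (x - min) / (max - min) + low`. Values outside
#' the training extrema (possible on test data) are clipped to
#' \[`low`, `high`\] so downstream kernel distances stay bounded. Constant
#' training columns map to `low` everywhere.
#'
#' @param x Numeric matrix with the same columns as the fitted data.
#' @param params A `minmax_params` object from [fit_minmax()].
#' @return Matrix of the same shape with values in \[`low`, `high`\].
#' @export
transform_minmax <- function(x, params) {
  if (inherits(x, "labeled_dataset")) x <- x$x
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(params$min)) {
    err_validation(sprintf("expected %d columns, got %d",
                           length(params$min), ncol(x)))
  }
  rng <- params$max - params$min
  out <- x
  for (j in seq_len(ncol(x))) {
    out[, j] <- if (rng[j] == 0) {
      params$low
    } else {
      (params$high - params$low) * (x[, j] - params$min[j]) / rng[j] + params$low
    }
  }
  out[out < params$low] <- params$low
  out[out > params$high] <- params$high
  out
}

#' @export
predict.minmax_params <- function(object, newdata, ...) {
  transform_minmax(newdata, object)
}

#' @export
print.minmax_params <- function(x, ...) {
  cat(sprintf("Min-max normalization to [%g, %g] over %d features\n",
              x$low, x$high, length(x$min)))
  invisible(x)
}

#' Per-feature profile of a feature matrix
#'
#' Reports, for each column, the extrema, the mean, and how many values
#' exceed the mean — a descriptive companion to normalization.
#'
#' @param x A [labeled_dataset] or numeric matrix.
#' @return Data frame with one row per feature.
#' @export
minmax_profile <- function(x) {
  if (inherits(x, "labeled_dataset")) x <- x$x
  data.frame(feature = colnames(x) %||% paste0("f", seq_len(ncol(x))),
             min = apply(x, 2L, min), max = apply(x, 2L, max),
             mean = colMeans(x),
             n_above_mean = vapply(seq_len(ncol(x)),
                                   function(j) sum(x[, j] > mean(x[, j])),
                                   integer(1)),
             row.names = NULL)
}
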