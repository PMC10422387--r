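#' Generate a synthetic imbalanced classification dataset
#'
#' Emulates the structure of benchmark imbalanced tabular datasets: a subset
#' of class-informative features whose class-conditional distributions are
#' Gaussians with means separated by `class_separation` along every
#' informative axis, plus class-independent Gaussian noise features. Class
#' sizes are set deterministically from `imbalance_ratio`, so the realized
#' ratio matches the request up to integer rounding; rows are then shuffled.
#'
#' The indices of the informative columns are recorded in the
#' `"informative"` attribute of the result (ground truth for feature
#' selection experiments).
#'
#' @param n_instances Total number of rows (default 200).
#' @param n_features Number of feature columns (default 10).
#' @param n_informative Number of class-informative columns,
#'   `1 <= n_informative <= n_features` (default 3).
#' @param imbalance_ratio Majority/minority size ratio, `>= 1` (default 3).
#' @param class_separation Euclidean distance between the mean vectors of
#'   consecutive classes (default 4). The mean difference lies entirely in
#'   the informative subspace, split equally over the informative axes, so
#'   with `noise_sd = 1` a separation of `s` means the class centroids are
#'   `s` standard deviations apart.
#' @param noise_sd Standard deviation of every feature around its class mean
#'   (default 1).
#' @param n_classes Number of classes (default 2). For more than two, the
#'   non-minority instances are split evenly among classes `0..C-2` and the
#'   minority is class `C-1`.
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return A [labeled_dataset]; the minority class is the positive class.
#' @export
generate_synthetic <- function(n_instances = 200, n_features = 10,
                               n_informative = 3, imbalance_ratio = 3,
                               class_separation = 4, noise_sd = 1,
                               n_classes = 2, seed = 1) {
  if (n_informative < 1L) err_config("n_informative must be >= 1")
  if (n_informative > n_features) {
    err_config("n_informative must not exceed n_features")
  }
  if (imbalance_ratio < 1) err_config("imbalance_ratio must be >= 1")
  if (noise_sd <= 0) err_config("noise_sd must be > 0")
  if (class_separation <= 0) err_config("class_separation must be > 0")
  C <- as.integer(n_classes)
  if (C < 2L) err_config("n_classes must be >= 2")

  # minority gets n/(1 + IR*(C-1)) rounded; remainder split over the others
  n_min <- max(1L, round(n_instances / (1 + imbalance_ratio * (C - 1))))
  n_rest <- n_instances - n_min
  sizes <- c(rep(n_rest %/% (C - 1L), C - 1L), n_min)
  extra <- n_rest - sum(sizes[seq_len(C - 1L)])
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

  y <- rep.int(seq_len(C) - 1L, times = sizes)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_instances * n_features, sd = noise_sd),
                n_instances, n_features)
    delta <- class_separation * noise_sd / sqrt(n_informative)
    for (j in seq_len(n_informative)) X[, j] <- X[, j] + y * delta
    ord <- sample.int(n_instances)
  })
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  ds <- labeled_dataset(X, y,
                        feature_names = paste0("f", seq_len(n_features)),
                        class_names = paste0("class", seq_len(C) - 1L),
                        positive_class = C - 1L)
  attr(ds, "informative") <- seq_len(n_informative)
  ds
}
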