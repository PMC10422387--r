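#' Degree of class imbalance
#'
#' `d = ms / ml`, the minority-to-majority size ratio; `d` lies in (0, 1]
#' and equals 1 for perfectly balanced data. Oversampling is triggered only
#' when `d` falls below the tolerance threshold `dth`.
#'
#' @param counts A `class_counts` object (see [class_counts()]).
#' @return `ms / ml` in (0, 1].
#' @export
degree_of_imbalance <- function(counts) {
  if (inherits(counts, "labeled_dataset")) counts <- class_counts(counts)
  if (counts$ml < 1L) err_validation("majority class is empty")
  if (counts$ms < 1L) err_validation("minority class is empty")
  counts$ms / counts$ml
}

#' Total number of synthetic samples to generate
#'
#' `G = round((ml - ms) * beta)`. With `beta = 1` the minority class is
#' brought up to the majority size (a completely balanced set, up to the
#' integer rounding of the per-point allocations).
#'
#' @param counts A `class_counts` object.
#' @param beta Balance level in \[0, 1\].
#' @return Integer `G >= 0`.
#' @export
required_synthetic_total <- function(counts, beta = 1) {
  if (beta < 0 || beta > 1) err_config("beta must lie in [0, 1]")
  as.integer(round((counts$ml - counts$ms) * beta))
}

#' Per-minority-point hardness ratios
#'
#' For each minority instance, finds its `k` nearest neighbours among all
#' other instances (Euclidean distance, ties broken toward the lower row
#' index) and counts how many belong to the majority class. The hardness
#' ratio `r_i = Delta_i / k` estimates how difficult the point is to learn:
#' 1 means the point sits entirely inside majority territory.
#'
#' @param ds Binary [labeled_dataset].
#' @param k Neighbour count (default 5); must be `< m`.
#' @return List with `delta` (majority-neighbour counts) and `r`
#'   (ratios in \[0, 1\]), ordered as the minority rows appear in `ds`.
#' @export
hardness_ratios <- function(ds, k = 5) {
  if (n_classes(ds) > 2L) err_validation("binary dataset required")
  m <- nrow(ds$x)
  if (k >= m) err_config(sprintf("k = %d must be < m = %d", k, m))
  cc <- class_counts(ds)
  min_idx <- which(ds$y == cc$minority)
  d2 <- cross_sqdist(ds$x[min_idx, , drop = FALSE], ds$x)
  delta <- integer(length(min_idx))
  for (ii in seq_along(min_idx)) {
    d <- d2[ii, ]
    d[min_idx[ii]] <- Inf                     # exclude the point itself
    nn <- order(d)[seq_len(k)]                # order() ties -> lower index
    delta[ii] <- sum(ds$y[nn] != cc$minority)
  }
  list(delta = delta, r = delta / k)
}

#' Normalize hardness ratios and allocate synthetic counts
#'
#' `r_hat_i = r_i / sum(r)` turns the ratios into a density over minority
#' points; the allocation is `g_i = floor(r_hat_i * G + 0.5)`. When every
#' ratio is zero (no minority point has majority neighbours) the density is
#' undefined and a uniform allocation `r_hat_i = 1/ms` is used instead, so
#' the balance contract of `beta = 1` is preserved.
#'
#' Because each `g_i` is rounded independently, `sum(g)` may differ from `G`
#' by at most `ms/2`; the literal per-point rounding is kept rather than
#' redistributing remainders.
#'
#' @param r Hardness ratio vector.
#' @param G Total synthetic count.
#' @return List with `r_hat` (sums to 1) and integer allocations `g`.
#' @export
adasyn_allocate <- function(r, G) {
  if (!length(r)) err_validation("empty ratio vector")
  if (G < 0) err_config("G must be >= 0")
  r_hat <- if (sum(r) > 0) r / sum(r) else rep.int(1 / length(r), length(r))
  g <- as.integer(floor(r_hat * G + 0.5))
  list(r_hat = r_hat, g = g)
}

#' Interpolate a synthetic point between two parents
#'
#' `s = x + (xz - x) * lambda`, componentwise, so `s` lies on the segment
#' between `x` and its minority neighbour `xz`.
#'
#' @param x,xz Parent feature vectors of equal length.
#' @param lambda Interpolation weight in \[0, 1\].
#' @return Numeric vector of the same length.
#' @export
synthesize_point <- function(x, xz, lambda) {
  if (length(x) != length(xz)) err_validation("parent dimension mismatch")
  if (lambda < 0 || lambda > 1) err_config("lambda must lie in [0, 1]")
  x + (xz - x) * lambda
}

#' ADASYN adaptive synthetic oversampling
#'
#' Decides from the degree of imbalance `d = ms/ml` whether to oversample
#' (only when `d < dth`), allocates synthetic minority samples in proportion
#' to each minority point's hardness ratio, and synthesizes each sample by
#' convex interpolation between a minority point and one of its `k` nearest
#' minority neighbours. Original rows are preserved in order; synthetics are
#' appended with the minority label.
#'
#' Neighbourhoods for the hardness ratios are searched over all classes;
#' interpolation partners are drawn from minority-only neighbours. A
#' minority point with no minority neighbour (e.g. a singleton minority
#' class) is duplicated unchanged, with a warning.
#'
#' @param ds Binary [labeled_dataset]; operates on raw features by default
#'   (normalize first and pass the transformed data for the alternative
#'   ordering).
#' @param k Neighbour count (default 5).
#' @param beta Balance level in \[0, 1\] (default 1, full balance).
#' @param dth Imbalance tolerance threshold in (0, 1\] (default 0.75):
#'   datasets with `d >= dth` are returned unchanged.
#' @param seed RNG seed for neighbour choice and interpolation weights.
#' @return Object of class `adasyn_result`: a list with `data` (the
#'   augmented [labeled_dataset]) and `plan` (class `adasyn_plan`, holding
#'   `d`, `G`, `delta`, `r`, `r_hat`, `g`, and per-synthetic parent indices
#'   and lambdas for audit).
#' @export
adasyn <- function(ds, k = 5, beta = 1, dth = 0.75, seed = 1) {
  if (n_classes(ds) > 2L) {
    err_validation("binary dataset required for ADASYN (got > 2 classes)")
  }
  if (dth <= 0 || dth > 1) err_config("dth must lie in (0, 1]")
  if (k < 1) err_config("k must be >= 1")
  cc <- class_counts(ds)
  d <- degree_of_imbalance(cc)
  plan_skip <- function() {
    structure(list(d = d, G = 0L, delta = integer(0), r = numeric(0),
                   r_hat = numeric(0), g = integer(0),
                   parents = matrix(integer(0), 0, 2), lambda = numeric(0),
                   minority = cc$minority),
              class = "adasyn_plan")
  }
  if (d >= dth) {
    return(structure(list(data = ds, plan = plan_skip()),
                     class = "adasyn_result"))
  }
  G <- required_synthetic_total(cc, beta)
  hr <- hardness_ratios(ds, k = k)
  al <- adasyn_allocate(hr$r, G)
  min_idx <- which(ds$y == cc$minority)

  # minority-only neighbour lists (ties toward lower row index)
  Xmin <- ds$x[min_idx, , drop = FALSE]
  d2 <- cross_sqdist(Xmin, Xmin)
  diag(d2) <- Inf
  kk <- min(k, length(min_idx) - 1L)
  if (kk < 1L) {
    warning("minority class has a single instance; synthetics duplicate it")
  }

  total <- sum(al$g)
  syn <- matrix(NA_real_, total, ncol(ds$x))
  parents <- matrix(NA_integer_, total, 2)
  lambdas <- numeric(total)
  with_seed(seed, {
    row <- 0L
    for (ii in seq_along(min_idx)) {
      gi <- al$g[ii]
      if (gi == 0L) next
      nbrs <- if (kk >= 1L) order(d2[ii, ])[seq_len(kk)] else integer(0)
      for (s in seq_len(gi)) {
        row <- row + 1L
        lam <- stats::runif(1)
        if (length(nbrs)) {
          zi <- nbrs[sample.int(length(nbrs), 1L)]
          syn[row, ] <- synthesize_point(Xmin[ii, ], Xmin[zi, ], lam)
          parents[row, ] <- c(min_idx[ii], min_idx[zi])
        } else {
          syn[row, ] <- Xmin[ii, ]
          parents[row, ] <- c(min_idx[ii], min_idx[ii])
        }
        lambdas[row] <- lam
      }
    }
  })
  out <- labeled_dataset(rbind(ds$x, syn),
                         c(ds$y, rep.int(cc$minority, total)),
                         feature_names = ds$feature_names,
                         class_names = ds$class_names,
                         positive_class = ds$positive_class)
  plan <- structure(list(d = d, G = G, delta = hr$delta, r = hr$r,
                         r_hat = al$r_hat, g = al$g, parents = parents,
                         lambda = lambdas, minority = cc$minority),
                    class = "adasyn_plan")
  structure(list(data = out, plan = plan), class = "adasyn_result")
}

#' @export
print.adasyn_plan <- function(x, ...) {
  cat(sprintf("ADASYN plan: d = %.4f, G = %d, %d minority points, %d synthetics\n",
              x$d, x$G, length(x$g), sum(x$g)))
  invisible(x)
}

#' @export
print.adasyn_result <- function(x, ...) {
  print(x$plan)
  print(x$data)
  invisible(x)
}
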