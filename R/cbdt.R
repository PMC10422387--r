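# Clustering-based decision tree: k-means partition of the training space
# with one gain-ratio (entropy-based, C4.5-style) decision tree per
# cluster; test points are routed to the tree of their nearest centroid.

# k-means++ seeding: first centre uniform, subsequent centres with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_centers <- function(X, k) {
  m <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(m, 1L)
  centers[1L, ] <- X[idx, ]
  if (k > 1L) {
    d2 <- cross_sqdist(X, centers[1L, , drop = FALSE])[, 1L]
    for (i in 2:k) {
      if (all(d2 == 0)) idx <- sample.int(m, 1L)
      else idx <- sample.int(m, 1L, prob = d2)
      centers[i, ] <- X[idx, ]
      d2 <- pmin(d2, cross_sqdist(X, centers[i, , drop = FALSE])[, 1L])
    }
  }
  centers
}

# Gain-ratio binary tree on numeric features.  At each node every feature's
# candidate thresholds (midpoints between consecutive distinct sorted
# values, respecting min_leaf) are scored by information gain divided by
# split information; the best positive-gain split wins, ties toward the
# lower feature index then lower threshold.
grow_tree <- function(X, y, C, depth, max_depth, min_leaf) {
  counts <- tabulate(y + 1L, nbins = C)
  m <- length(y)
  leaf <- list(leaf = TRUE, counts = counts)
  if (m < 2L * min_leaf || depth >= max_depth || sum(counts > 0L) < 2L) {
    return(leaf)
  }
  H <- entropy2(counts)
  best <- NULL
  best_gr <- 0
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]
    ys <- y[ord]
    # cumulative class counts after each position
    cum <- sapply(seq_len(C) - 1L, function(c) cumsum(ys == c))
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = m)
    cand <- which(xs[-m] < xs[-1])
    cand <- cand[cand >= min_leaf & (m - cand) >= min_leaf]
    if (!length(cand)) next
    L <- cum[cand, , drop = FALSE]
    R <- matrix(counts, length(cand), C, byrow = TRUE) - L
    nl <- cand
    nr <- m - cand
    hl <- row_count_entropy(L, nl)
    hr <- row_count_entropy(R, nr)
    gain <- H - (nl / m) * hl - (nr / m) * hr
    pi_l <- nl / m
    si <- -(pi_l * log2(pi_l) + (1 - pi_l) * log2(1 - pi_l))
    gr <- ifelse(gain > 1e-12, gain / si, -Inf)
    bi <- which.max(gr)
    if (is.finite(gr[bi]) && gr[bi] > best_gr + 1e-12) {
      best_gr <- gr[bi]
      i <- cand[bi]
      best <- list(j = j, thr = (xs[i] + xs[i + 1]) / 2)
    }
  }
  if (is.null(best)) return(leaf)
  go_left <- X[, best$j] <= best$thr
  list(leaf = FALSE, j = best$j, thr = best$thr,
       left = grow_tree(X[go_left, , drop = FALSE], y[go_left], C,
                        depth + 1L, max_depth, min_leaf),
       right = grow_tree(X[!go_left, , drop = FALSE], y[!go_left], C,
                         depth + 1L, max_depth, min_leaf))
}

# Route rows to leaves; returns a matrix of Laplace-smoothed leaf
# class frequencies, one row per instance.
tree_proba <- function(node, X, C) {
  m <- nrow(X)
  out <- matrix(NA_real_, m, C)
  if (m == 0L) return(out)
  if (node$leaf) {
    p <- (node$counts + 1) / (sum(node$counts) + C)
    out[] <- rep(p, each = m)
    return(out)
  }
  go_left <- X[, node$j] <= node$thr
  out[go_left, ] <- tree_proba(node$left, X[go_left, , drop = FALSE], C)
  out[!go_left, ] <- tree_proba(node$right, X[!go_left, , drop = FALSE], C)
  out
}

#' Fit a clustering-based decision tree classifier
#'
#' Partitions the training rows into `k` clusters by k-means (k-means++
#' seeding, at most 300 Lloyd iterations, deterministic given `seed`), then
#' grows one gain-ratio decision tree per non-empty cluster (entropy-based
#' binary splits, minimum leaf size 2, maximum depth 10). A cluster whose
#' rows all share one class yields a single majority leaf. Empty clusters
#' are dropped with a message.
#'
#' @param ds Normalized [labeled_dataset].
#' @param k Cluster count (default 3); must not exceed the instance count.
#' @param seed RNG seed for the k-means seeding.
#' @param max_depth,min_leaf Tree growth limits (defaults 10, 2).
#' @return Object of class `cbdt` with centroids and per-cluster trees.
#' @export
fit_cbdt <- function(ds, k = 3, seed = 1, max_depth = 10, min_leaf = 2) {
  m <- nrow(ds$x)
  if (k > m) err_config(sprintf("k = %d exceeds instance count %d", k, m))
  C <- n_classes(ds)
  if (k == 1L) {
    assign_ <- rep.int(1L, m)
    centers <- matrix(colMeans(ds$x), 1L)
  } else {
    km <- with_seed(seed, {
      init <- kmeanspp_centers(ds$x, k)
      suppressWarnings(stats::kmeans(ds$x, centers = init, iter.max = 300))
    })
    assign_ <- km$cluster
    centers <- km$centers
  }
  keep <- sort(unique(assign_))
  if (length(keep) < nrow(centers)) {
    message(sprintf("dropping %d empty cluster(s)",
                    nrow(centers) - length(keep)))
  }
  trees <- lapply(keep, function(cl) {
    rows <- assign_ == cl
    grow_tree(ds$x[rows, , drop = FALSE], ds$y[rows], C, 0L,
              max_depth, min_leaf)
  })
  structure(list(centers = centers[keep, , drop = FALSE], trees = trees,
                 k = length(keep), class_names = ds$class_names,
                 positive_class = ds$positive_class),
            class = "cbdt")
}

#' Predict class probabilities with a clustering-based decision tree
#'
#' Each query row is routed to the tree of its nearest centroid (Euclidean
#' distance); the returned probabilities are the Laplace-smoothed class
#' frequencies of the leaf it lands in.
#'
#' @param object A `cbdt` model.
#' @param newdata Numeric matrix with the training columns.
#' @param type `"prob"` (default) or `"class"`.
#' @param ... Unused.
#' @export
predict.cbdt <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$x
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != ncol(object$centers)) {
    err_validation(sprintf("expected %d columns, got %d",
                           ncol(object$centers), ncol(newdata)))
  }
  C <- length(object$class_names)
  nearest <- max.col(-cross_sqdist(newdata, object$centers),
                     ties.method = "first")
  out <- matrix(NA_real_, nrow(newdata), C)
  for (cl in seq_len(object$k)) {
    rows <- nearest == cl
    if (any(rows)) {
      out[rows, ] <- tree_proba(object$trees[[cl]],
                                newdata[rows, , drop = FALSE], C)
    }
  }
  colnames(out) <- object$class_names
  if (type == "class") predict_label(out) else out
}
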