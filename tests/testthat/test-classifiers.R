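prob_matrix_ok <- function(p) {
  all(p >= 0 & p <= 1) && max(abs(rowSums(p) - 1)) < 1e-9
}

# ---- PNN ----------------------------------------------------------------

test_that("PNN stores all points, class priors, and validates classes", {
  ds <- norm_ds(generate_synthetic(n_instances = 50, n_features = 3, seed = 2))
  fit <- fit_pnn(ds)
  expect_equal(nrow(fit$x), 50L)
  expect_equal(unname(fit$priors),
               unname(tabulate(ds$y + 1L, nbins = 2) / 50))
  expect_error(fit_pnn(ds, sigma = 0), class = "asdmlc_config_error")
})

test_that("PNN probabilities respect symmetry and proximity", {
  ds <- labeled_dataset(matrix(c(0, 1), ncol = 1), c(0L, 1L),
                        class_names = c("a", "b"))
  fit <- fit_pnn(ds, sigma = 0.1)
  p_mid <- predict(fit, matrix(0.5))
  expect_equal(unname(p_mid[1, ]), c(0.5, 0.5))   # equidistant, equal priors
  p_at <- predict(fit, matrix(0))
  expect_gt(p_at[1, 1], 0.99)                     # on top of class-a centre
  expect_true(prob_matrix_ok(predict(fit, matrix(runif(20)))))
})

test_that("PNN in the sigma -> 0 limit reproduces 1-nearest-neighbour", {
  set.seed(123)
  agree <- vapply(1:20, function(i) {
    X <- matrix(runif(40), 20, 2)
    y <- sample(0:1, 20, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- 1L - y[1]
    ds <- labeled_dataset(X, y, class_names = c("a", "b"))
    fit <- fit_pnn(ds, sigma = 1e-6)
    te <- matrix(runif(20), 10, 2)
    pred <- predict(fit, te, type = "class")
    nn <- apply(cross_sqdist_ref(te, X), 1L, which.min)
    mean(pred == y[nn])
  }, numeric(1))
  expect_equal(mean(agree), 1)
})

# ---- ANFIS --------------------------------------------------------------

test_that("ANFIS represents a linear target almost exactly (hybrid LSE)", {
  x <- matrix(seq(0, 1, length.out = 40), ncol = 1)
  ds <- labeled_dataset(rbind(x, x), c(rep(0L, 40), rep(1L, 40)),
                        class_names = c("a", "b"))
  # regression head check: target equals the input value
  head <- asdmlc:::anfis_head_fit(x, x[, 1], n_mf = 2, epochs = 5, lr = 0.01)
  expect_lt(head$mse, 1e-3)
})

test_that("ANFIS handles constant targets and is row-order invariant", {
  set.seed(4)
  X <- matrix(runif(60), 30, 2)
  y <- as.integer(X[, 1] > 0.5)
  if (length(unique(y)) < 2) y[1] <- 1L - y[1]
  ds <- labeled_dataset(X, y, class_names = c("a", "b"))
  fit <- fit_anfis(ds, epochs = 5)
  perm <- sample(30)
  ds2 <- labeled_dataset(X[perm, ], y[perm], class_names = c("a", "b"),
                         positive_class = ds$positive_class)
  fit2 <- fit_anfis(ds2, epochs = 5)
  grid <- matrix(runif(40), 20, 2)
  expect_equal(predict(fit, grid), predict(fit2, grid), tolerance = 1e-6)
  # constant-target head predicts ~1 everywhere
  h1 <- asdmlc:::anfis_head_fit(X, rep(1, 30), n_mf = 2, epochs = 3, lr = 0.01)
  expect_equal(asdmlc:::anfis_head_predict(h1, grid), rep(1, 20),
               tolerance = 1e-3)
})

test_that("ANFIS output is monotone on a monotone fixture and rows sum to 1", {
  # a representable increasing target: the fitted surface must be increasing
  x <- matrix(seq(0, 1, length.out = 60), ncol = 1)
  head <- asdmlc:::anfis_head_fit(x, x[, 1], n_mf = 2, epochs = 5, lr = 0.01)
  grid <- matrix(seq(0, 1, length.out = 101), ncol = 1)
  expect_true(all(diff(asdmlc:::anfis_head_predict(head, grid)) >= -1e-6))
  # step-labelled classes: monotone through the transition, 0.5 at the
  # symmetry point (first-order consequents may wiggle when extrapolating
  # at the domain edges, so the edge regions are not constrained)
  y <- as.integer(x[, 1] > 0.5)
  ds <- labeled_dataset(x, y, class_names = c("lo", "hi"))
  fit <- fit_anfis(ds, epochs = 20)
  p <- predict(fit, grid)
  expect_true(prob_matrix_ok(p))
  mid <- 31:71   # x in [0.3, 0.7]
  expect_true(all(diff(p[mid, 2]) >= -1e-6))
  expect_equal(unname(p[51, 2]), 0.5, tolerance = 0.05)
})

test_that("ANFIS refuses too many inputs with advice to select features", {
  ds <- norm_ds(generate_synthetic(n_instances = 60, n_features = 10, seed = 3))
  expect_error(fit_anfis(ds), regexp = "select",
               class = "asdmlc_config_error")
})

# ---- CBDT ---------------------------------------------------------------

test_that("k = 1 clustering-based tree equals a single plain tree", {
  ds <- norm_ds(generate_synthetic(n_instances = 150, n_features = 4,
                                   n_informative = 2, class_separation = 4,
                                   seed = 12))
  cb <- fit_cbdt(ds, k = 1, seed = 1)
  expect_equal(cb$k, 1L)
  tree <- asdmlc:::grow_tree(ds$x, ds$y, 2L, 0L, 10L, 2L)
  grid <- matrix(runif(80), 20, 4)
  expect_equal(predict(cb, grid), asdmlc:::tree_proba(tree, grid, 2L),
               ignore_attr = TRUE)
})

test_that("two separated blobs split into pure clusters under k = 2", {
  ds <- fixture_blobs(n = 100, sep = 12, seed = 6)
  cb <- fit_cbdt(ds, k = 2, seed = 3)
  # each blob's points route to one centroid, and predictions are correct
  pred <- predict(cb, ds$x, type = "class")
  expect_gte(mean(pred == ds$y), 0.98)
  nearest <- apply(cross_sqdist_ref(ds$x, cb$centers), 1L, which.min)
  expect_true(all(vapply(1:2, function(cl) {
    length(unique(ds$y[nearest == cl])) == 1L
  }, logical(1))))
})

test_that("tree split choice maximizes gain ratio (small-fixture oracle)", {
  X <- cbind(f1 = c(1, 2, 3, 4, 5, 6), f2 = c(1, 1, 2, 2, 3, 3))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  tree <- asdmlc:::grow_tree(X, y, 2L, 0L, 10L, 2L)
  expect_false(tree$leaf)
  expect_equal(tree$j, 1L)        # f1 splits perfectly at 3.5
  expect_equal(tree$thr, 3.5)
  # exhaustive oracle over both features' candidate thresholds
  gr_best <- 0; best <- NULL
  for (j in 1:2) for (i in 1:5) {
    if (X[order(X[, j])[i], j] == X[order(X[, j])[i + 1], j]) next
    ys <- y[order(X[, j])]
    l <- table(factor(ys[1:i], 0:1)); r <- table(factor(ys[-(1:i)], 0:1))
    H <- function(t) { p <- t[t > 0] / sum(t); -sum(p * log2(p)) }
    gain <- H(table(factor(y, 0:1))) - (i / 6) * H(l) - ((6 - i) / 6) * H(r)
    si <- H(c(i, 6 - i))
    if (gain > 1e-12 && gain / si > gr_best) {
      gr_best <- gain / si; best <- j
    }
  }
  expect_equal(tree$j, best)
})

test_that("CBDT predictions are valid probabilities with Laplace smoothing", {
  ds <- norm_ds(generate_synthetic(n_instances = 80, n_features = 3, seed = 9))
  cb <- fit_cbdt(ds, k = 3, seed = 2)
  p <- predict(cb, ds$x)
  expect_true(prob_matrix_ok(p))
  expect_true(all(p > 0))   # Laplace smoothing keeps probabilities off 0
  expect_error(fit_cbdt(ds, k = 81), class = "asdmlc_config_error")
})

test_that("CBDT with k = 1 tracks an independent recursive-partitioning oracle", {
  skip_if_not_installed("rpart")
  ds <- fixture_blobs(n = 200, sep = 8, d = 3, ir = 2, seed = 18)
  dn <- norm_ds(ds)
  cb <- fit_cbdt(dn, k = 1, seed = 1)
  acc_cb <- mean(predict(cb, dn$x, type = "class") == dn$y)
  df <- data.frame(dn$x, y = factor(dn$y))
  rp <- rpart::rpart(y ~ ., df, method = "class")
  acc_rp <- mean(as.integer(as.character(predict(rp, df, type = "class"))) == dn$y)
  expect_gte(acc_cb, acc_rp - 0.02)
  expect_gte(acc_cb, 0.95)
})

# ---- shared invariants --------------------------------------------------

test_that("all three members are label-permutation equivariant", {
  ds <- norm_ds(generate_synthetic(n_instances = 80, n_features = 3,
                                   n_informative = 2, class_separation = 4,
                                   seed = 44))
  flip <- labeled_dataset(ds$x, 1L - ds$y,
                          class_names = rev(ds$class_names),
                          positive_class = 1L - ds$positive_class)
  grid <- matrix(runif(30), 10, 3)
  for (fitter in list(function(d) fit_pnn(d),
                      function(d) fit_anfis(d, epochs = 5),
                      function(d) fit_cbdt(d, k = 2, seed = 7))) {
    p1 <- predict(fitter(ds), grid)
    p2 <- predict(fitter(flip), grid)
    # ANFIS is equivariant only up to its ridge stabilizer (the penalty is
    # not invariant under the affine flip of the target), hence the slack
    expect_equal(unname(p1), unname(p2[, c(2, 1)]), tolerance = 5e-3)
  }
})

test_that("each member alone reaches 0.95 accuracy on separable blobs under 10-fold CV", {
  ds <- norm_ds(fixture_blobs(n = 150, sep = 8, d = 2, ir = 1.5, seed = 10))
  fold <- asdmlc:::stratified_folds(ds$y, 10, seed = 1)
  for (fitter in list(function(d) fit_pnn(d),
                      function(d) fit_anfis(d, epochs = 5),
                      function(d) fit_cbdt(d, k = 2, seed = 3))) {
    correct <- 0L
    for (f in 1:10) {
      tr <- fold != f
      dtr <- labeled_dataset(ds$x[tr, ], ds$y[tr],
                             class_names = ds$class_names,
                             positive_class = ds$positive_class)
      pred <- predict(fitter(dtr), ds$x[!tr, , drop = FALSE], type = "class")
      correct <- correct + sum(pred == ds$y[!tr])
    }
    expect_gte(correct / length(ds$y), 0.95)
  }
})

test_that("a single-class cluster yields that class with (smoothed) certainty", {
  X <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1)
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  ds <- labeled_dataset(X, y, class_names = c("a", "b"))
  cb <- fit_cbdt(ds, k = 2, seed = 1)
  p <- predict(cb, matrix(c(0.05, 5.05), ncol = 1))
  expect_equal(predict_label(p), c(0L, 1L))
  expect_true(all(apply(p, 1, max) > 0.7))
})
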