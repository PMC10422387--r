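make_counts <- function(ms, ml) {
  structure(list(ms = as.integer(ms), ml = as.integer(ml),
                 m = as.integer(ms + ml), minority = 1L, multiclass = FALSE),
            class = "class_counts")
}

test_that("degree of imbalance is ms/ml", {
  expect_equal(degree_of_imbalance(make_counts(50, 50)), 1)
  expect_equal(degree_of_imbalance(make_counts(268, 500)), 0.536)
  expect_equal(degree_of_imbalance(make_counts(1, 100)), 0.01)
})

test_that("required synthetic total is round((ml - ms) * beta)", {
  expect_equal(required_synthetic_total(make_counts(268, 500), 1), 232L)
  expect_equal(required_synthetic_total(make_counts(100, 100), 0.7), 0L)
  expect_equal(required_synthetic_total(make_counts(100, 300), 0.5), 100L)
  expect_error(required_synthetic_total(make_counts(1, 2), 1.5),
               class = "asdmlc_config_error")
})

test_that("hardness ratios match a brute-force neighbour count on the 1-D fixture", {
  ds <- fixture_1d()
  hr <- hardness_ratios(ds, k = 2)
  # brute force: each minority point has exactly one minority neighbour
  # (the other), so its second-nearest neighbour is the majority point at
  # 0.9 -> delta = 1 for both
  expect_equal(hr$delta, c(1L, 1L))
  expect_equal(hr$r, c(0.5, 0.5))
  # k = 4 forces majority points into each neighbourhood: 4 nbrs = 1 min + 3 maj
  hr4 <- hardness_ratios(ds, k = 4)
  expect_equal(hr4$r, c(3 / 4, 3 / 4))
  expect_error(hardness_ratios(ds, k = 5), class = "asdmlc_config_error")
})

test_that("hardness ratios agree with an exhaustive pairwise-distance oracle", {
  ds <- generate_synthetic(n_instances = 60, n_features = 3,
                           imbalance_ratio = 3, class_separation = 2, seed = 13)
  k <- 5
  hr <- hardness_ratios(ds, k = k)
  cc <- class_counts(ds)
  min_idx <- which(ds$y == cc$minority)
  oracle <- vapply(min_idx, function(i) {
    d <- apply(ds$x, 1L, function(row) sqrt(sum((row - ds$x[i, ])^2)))
    d[i] <- Inf
    nn <- order(d)[1:k]
    sum(ds$y[nn] != cc$minority)
  }, numeric(1))
  expect_equal(hr$delta, as.integer(oracle))
})

test_that("allocation normalizes ratios and falls back to uniform when all are zero", {
  al <- adasyn_allocate(c(1, 1), 10)
  expect_equal(al$r_hat, c(0.5, 0.5))
  expect_equal(al$g, c(5L, 5L))
  expect_equal(adasyn_allocate(c(0.8, 0.2), 10)$g, c(8L, 2L))
  al0 <- adasyn_allocate(c(0, 0), 4)
  expect_equal(al0$r_hat, c(0.5, 0.5))
  expect_equal(al0$g, c(2L, 2L))
  expect_equal(sum(adasyn_allocate(c(0.3, 0.3, 0.4), 100)$r_hat), 1)
  expect_error(adasyn_allocate(numeric(0), 5),
               class = "asdmlc_validation_error")
})

test_that("synthetic points interpolate the parent segment", {
  expect_equal(synthesize_point(c(1, 2), c(3, 4), 0), c(1, 2))
  expect_equal(synthesize_point(c(1, 2), c(3, 4), 1), c(3, 4))
  expect_equal(synthesize_point(c(0, 0), c(2, 4), 0.25), c(0.5, 1.0))
  expect_error(synthesize_point(c(1, 2), c(1, 2, 3), 0.5),
               class = "asdmlc_validation_error")
})

test_that("balanced input passes through untouched (d >= dth)", {
  ds <- generate_synthetic(n_instances = 100, imbalance_ratio = 1.2, seed = 2)
  out <- adasyn(ds, dth = 0.75, seed = 1)
  expect_identical(out$data$x, ds$x)
  expect_equal(out$plan$G, 0L)
})

test_that("the 1-D fixture gains ml - ms synthetics (up to rounding) inside minority segments", {
  ds <- fixture_1d()
  out <- adasyn(ds, k = 2, beta = 1, seed = 4)
  syn <- out$data$x[-(1:5), , drop = FALSE]
  # G = ml - ms = 1; the uniform fallback gives each minority point
  # g = floor(0.5 * 1 + 0.5) = 1, so |sum(g) - G| = 1 <= ms per the
  # documented per-point rounding (no remainder redistribution)
  expect_equal(nrow(syn), 2L)
  expect_lte(abs(nrow(syn) - 1L), class_counts(ds)$ms)
  # the only feasible segment is [0.0, 0.1]
  expect_gte(min(syn), 0.0)
  expect_lte(max(syn), 0.1)
  expect_equal(out$data$y[6], 1L)
})

test_that("oversampling preserves originals, appends minority-only synthetics in-hull", {
  ds <- generate_synthetic(n_instances = 300, n_features = 5,
                           imbalance_ratio = 4, class_separation = 3, seed = 17)
  out <- adasyn(ds, beta = 1, seed = 6)
  m <- nrow(ds$x)
  expect_identical(out$data$x[1:m, ], ds$x)
  expect_identical(out$data$y[1:m], ds$y)
  syn_rows <- seq_len(nrow(out$data$x))[-(1:m)]
  cc <- class_counts(ds)
  expect_true(all(out$data$y[syn_rows] == cc$minority))
  # componentwise hull of the recorded parents
  for (i in seq_along(syn_rows)) {
    pa <- out$plan$parents[i, ]
    lo <- pmin(ds$x[pa[1], ], ds$x[pa[2], ])
    hi <- pmax(ds$x[pa[1], ], ds$x[pa[2], ])
    expect_true(all(out$data$x[syn_rows[i], ] >= lo - 1e-12 &
                      out$data$x[syn_rows[i], ] <= hi + 1e-12))
  }
})

test_that("hard minority points receive at least the easy points' allocation", {
  # one minority point surrounded by majority (hard), one in a minority
  # clump (easy); oracle = direct evaluation of the ratio/allocation rules
  X <- matrix(c(0.00, 0.05, 0.10, 0.15,   # minority clump
                5.00,                      # hard minority point
                5.10, 5.20, 4.90, 4.80, 5.05, 0.5, 0.6, 0.7, 0.8),
              ncol = 1)
  y <- c(1L, 1L, 1L, 1L, 1L, rep(0L, 9))
  ds <- labeled_dataset(X, y, class_names = c("maj", "min"))
  hr <- hardness_ratios(ds, k = 3)
  al <- adasyn_allocate(hr$r, 20)
  hard <- which(ds$x[ds$y == 1L, 1] == 5.00)
  easy <- 1L
  expect_equal(hr$r[hard], 1)
  expect_equal(hr$r[easy], 0)
  expect_gte(al$g[hard], al$g[easy])
  # monotone: allocations ordered like the ratios
  expect_true(all(diff(al$g[order(hr$r)]) >= 0))
})

test_that("adasyn is deterministic given the seed and balances at beta = 1", {
  ds <- generate_synthetic(n_instances = 600, n_features = 8,
                           imbalance_ratio = 5, class_separation = 3, seed = 31)
  a <- adasyn(ds, beta = 1, seed = 9)
  b <- adasyn(ds, beta = 1, seed = 9)
  expect_identical(a$data$x, b$data$x)
  cc_out <- class_counts(a$data)
  cc_in <- class_counts(ds)
  expect_lte(abs(cc_out$ml - cc_out$ms), cc_in$ms)  # rounding slack
})

test_that("a singleton minority class is duplicated with a warning", {
  X <- matrix(rnorm(20), ncol = 2)
  y <- c(1L, rep(0L, 9))
  ds <- labeled_dataset(X, y, class_names = c("maj", "min"))
  expect_warning(out <- adasyn(ds, k = 3, beta = 1, seed = 1),
                 regexp = "single instance")
  syn <- out$data$x[-(1:10), , drop = FALSE]
  expect_true(all(apply(syn, 1L, function(s) all(s == X[1, ]))))
})

test_that("multiclass input is rejected with a binary-required error", {
  ds <- generate_synthetic(n_instances = 90, n_classes = 3, seed = 8)
  expect_error(adasyn(ds), regexp = "binary",
               class = "asdmlc_validation_error")
})
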