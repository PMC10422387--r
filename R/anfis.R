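# First-order Sugeno ANFIS with grid-partitioned Gaussian memberships.
#
# Five-layer forward pass: (1) Gaussian membership grades per input, (2)
# rule firing strengths as products across inputs, (3) normalization of
# firing strengths, (4) first-order rule consequents weighted by normalized
# strengths, (5) sum. Hybrid training: consequents by (ridge-stabilized)
# least squares given the current premises, premises by batch gradient
# descent on the squared error of a 0/1 class target.

anfis_memberships <- function(x, centers, sigmas) {
  # x: m-vector for one input; centers/sigmas: n_mf vectors -> m x n_mf
  d <- outer(x, centers, "-")
  exp(-sweep(d^2, 2L, 2 * sigmas^2, "/"))
}

anfis_forward <- function(X, prem, rules) {
  m <- nrow(X)
  R <- nrow(rules)
  W <- matrix(1, m, R)
  for (j in seq_len(ncol(X))) {
    Mj <- anfis_memberships(X[, j], prem$centers[[j]], prem$sigmas[[j]])
    W <- W * Mj[, rules[, j], drop = FALSE]
  }
  Sw <- rowSums(W) + 1e-12
  list(W = W, Wn = W / Sw, Sw = Sw)
}

anfis_design <- function(X, Wn) {
  m <- nrow(X)
  R <- ncol(Wn)
  X1 <- cbind(X, 1)
  p <- ncol(X1)
  A <- matrix(0, m, R * p)
  for (r in seq_len(R)) A[, ((r - 1) * p + 1):(r * p)] <- Wn[, r] * X1
  A
}

anfis_head_fit <- function(X, t, n_mf, epochs, lr) {
  n <- ncol(X)
  rng <- apply(X, 2L, range)
  prem <- list(
    centers = lapply(seq_len(n), function(j) {
      if (rng[1, j] == rng[2, j]) rng[1, j] + c(-0.5, 0.5)
      else seq(rng[1, j], rng[2, j], length.out = n_mf)
    }),
    sigmas = lapply(seq_len(n), function(j) {
      s <- max(rng[2, j] - rng[1, j], 1e-3) / max(n_mf - 1, 1) / sqrt(2)
      rep(s, n_mf)
    }))
  rules <- as.matrix(expand.grid(rep(list(seq_len(n_mf)), n)))
  dimnames(rules) <- NULL
  R <- nrow(rules)
  p <- n + 1L
  theta <- numeric(R * p)
  X1 <- cbind(X, 1)
  m <- nrow(X)

  for (ep in seq_len(epochs)) {
    fw <- anfis_forward(X, prem, rules)
    A <- anfis_design(X, fw$Wn)
    AtA <- crossprod(A)
    lam <- 1e-6 * max(1, mean(diag(AtA)))
    theta <- solve(AtA + lam * diag(ncol(A)), crossprod(A, t))
    Fr <- X1 %*% matrix(theta, p, R)          # rule outputs f_r(x), m x R
    yhat <- rowSums(fw$Wn * Fr)
    if (ep == epochs) break
    # premise gradient: dL/dw_r = (2e/m) * (f_r - yhat) / Sw
    e <- yhat - t
    Tm <- (2 * e / m) * (Fr - yhat) / fw$Sw   # m x R, columns recycled
    TW <- Tm * fw$W
    for (j in seq_len(n)) {
      for (k in seq_len(n_mf)) {
        rk <- which(rules[, j] == k)
        g <- rowSums(TW[, rk, drop = FALSE])
        cjk <- prem$centers[[j]][k]
        sjk <- prem$sigmas[[j]][k]
        diff <- X[, j] - cjk
        prem$centers[[j]][k] <- cjk - lr * sum(g * diff / sjk^2)
        prem$sigmas[[j]][k] <- max(1e-3,
                                   sjk - lr * sum(g * diff^2 / sjk^3))
      }
    }
  }
  list(prem = prem, rules = rules, theta = as.numeric(theta), mse = mean((yhat - t)^2))
}

anfis_head_predict <- function(head, X) {
  fw <- anfis_forward(X, head$prem, head$rules)
  p <- ncol(X) + 1L
  Fr <- cbind(X, 1) %*% matrix(head$theta, p, nrow(head$rules))
  rowSums(fw$Wn * Fr)
}

#' Fit an adaptive neuro-fuzzy inference system classifier
#'
#' First-order Sugeno ANFIS under grid partition: `n_mf` Gaussian
#' membership functions per input generate `n_mf^n_inputs` rules, each with
#' a first-order polynomial consequent. Training is hybrid: consequent
#' coefficients are solved by least squares given the current memberships,
#' then membership centres and widths take one batch gradient step per
#' epoch on the squared error against a 0/1 class target. For more than two
#' classes, independent one-vs-rest heads are fit and their outputs
#' renormalized.
#'
#' The rule count grows as `n_mf^n_inputs`, so the input dimension is
#' capped (`max_inputs`, default 8); feature selection upstream is the
#' intended way to meet the cap.
#'
#' @param ds Normalized [labeled_dataset].
#' @param epochs Training epochs (default 50).
#' @param lr Premise learning rate (default 0.01).
#' @param n_mf Membership functions per input (default 2).
#' @param max_inputs Hard cap on the number of inputs (default 8).
#' @return Object of class `anfis`.
#' @export
fit_anfis <- function(ds, epochs = 50, lr = 0.01, n_mf = 2, max_inputs = 8) {
  n <- ncol(ds$x)
  if (n > max_inputs) {
    err_config(sprintf(
      "%d inputs exceed the cap of %d (rule count %d^n explodes); select features first",
      n, max_inputs, n_mf))
  }
  C <- n_classes(ds)
  heads <- if (C == 2L) {
    list(anfis_head_fit(ds$x, as.numeric(ds$y == 1L), n_mf, epochs, lr))
  } else {
    lapply(seq_len(C) - 1L, function(c) {
      anfis_head_fit(ds$x, as.numeric(ds$y == c), n_mf, epochs, lr)
    })
  }
  structure(list(heads = heads, n_inputs = n, n_mf = n_mf,
                 class_names = ds$class_names,
                 positive_class = ds$positive_class),
            class = "anfis")
}

#' Predict class probabilities with an ANFIS model
#'
#' The Sugeno output is a real number; for binary data it is clipped to
#' \[0, 1\] and read as the probability of class 1, giving rows
#' `(1 - p, p)`. One-vs-rest heads (more than two classes) are clipped and
#' renormalized; an all-zero row falls back to uniform.
#'
#' @param object An `anfis` model.
#' @param newdata Numeric matrix with the training columns.
#' @param type `"prob"` (default) or `"class"`.
#' @param ... Unused.
#' @export
predict.anfis <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$x
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_inputs) {
    err_validation(sprintf("expected %d columns, got %d",
                           object$n_inputs, ncol(newdata)))
  }
  C <- length(object$class_names)
  if (C == 2L) {
    p <- pmin(pmax(anfis_head_predict(object$heads[[1]], newdata), 0), 1)
    out <- cbind(1 - p, p)
  } else {
    raw <- sapply(object$heads, function(h) anfis_head_predict(h, newdata))
    raw <- matrix(pmin(pmax(raw, 0), 1), nrow = nrow(newdata))
    s <- rowSums(raw)
    out <- raw / pmax(s, .Machine$double.eps)
    out[s == 0, ] <- 1 / C
  }
  colnames(out) <- object$class_names
  if (type == "class") predict_label(out) else out
}
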