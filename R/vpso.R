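#' Linearly decaying inertia weight
#'
#' `w = (wmax - wmin) * (imax - i) / imax + wmin`: starts at `wmax` when
#' `i = 0` and reaches `wmin` at the final iteration, shifting the swarm
#' from exploration toward exploitation.
#'
#' @param i Current iteration, `0 <= i <= imax`.
#' @param imax Maximum iteration count, `> 0`.
#' @param wmax,wmin Inertia bounds (defaults 0.9, 0.5).
#' @return Inertia weight in `[wmin, wmax]`.
#' @export
inertia_weight <- function(i, imax, wmax = 0.9, wmin = 0.5) {
  if (imax <= 0) err_config("imax must be > 0")
  (wmax - wmin) * (imax - i) / imax + wmin
}

#' Per-dimension velocity equalization
#'
#' Any velocity component exceeding the cap in magnitude is damped by the
#' factor `alpha`, repeatedly until it lies within `[-vmax, vmax]`. Unlike a
#' hard clamp, damping keeps the component's sign and relative ordering
#' while pulling every dimension back to a comparable velocity scale, which
#' delays premature convergence.
#'
#' @param v Velocity vector.
#' @param vmax Per-dimension cap (default 4).
#' @param alpha Damping factor in (0, 1) (default 0.5).
#' @return Velocity vector with `max(abs(v)) <= vmax`.
#' @export
equalize_velocity <- function(v, vmax = 4, alpha = 0.5) {
  if (alpha <= 0 || alpha >= 1) err_config("alpha must lie in (0, 1)")
  while (any(out <- abs(v) > vmax)) v[out] <- alpha * v[out]
  v
}

#' Particle velocity update
#'
#' The canonical particle swarm update
#' `v' = w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with fresh uniform
#' `r1, r2` per dimension, followed by velocity equalization (or a plain
#' clamp to `[-vmax, vmax]` when `equalize = FALSE`).
#'
#' @param v Current velocity vector.
#' @param x Current (binary) position.
#' @param pbest,gbest Personal and global best positions.
#' @param w Inertia weight for this iteration.
#' @param c1,c2 Acceleration constants (defaults 2, 2).
#' @param vmax Velocity cap (default 4).
#' @param alpha Equalization damping factor (default 0.5).
#' @param equalize Use damping-based equalization (default) or a hard clamp.
#' @param r1,r2 Optional fixed random vectors (drawn from the current RNG
#'   stream when `NULL`).
#' @return Updated velocity vector.
#' @export
update_velocity <- function(v, x, pbest, gbest, w, c1 = 2, c2 = 2,
                            vmax = 4, alpha = 0.5, equalize = TRUE,
                            r1 = NULL, r2 = NULL) {
  n <- length(v)
  r1 <- r1 %||% stats::runif(n)
  r2 <- r2 %||% stats::runif(n)
  v2 <- w * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)
  if (equalize) {
    equalize_velocity(v2, vmax = vmax, alpha = alpha)
  } else {
    pmin(pmax(v2, -vmax), vmax)
  }
}

#' Stochastic binarization of a velocity vector
#'
#' Standard binary-PSO transfer: bit j is set with probability
#' `sigmoid(v_j) = 1 / (1 + exp(-v_j))`. An all-zero draw is repaired by
#' setting one uniformly chosen bit, since an empty feature subset is not a
#' valid candidate.
#'
#' @param v Velocity vector.
#' @return Integer 0/1 vector with at least one set bit.
#' @export
binarize_position <- function(v) {
  p <- 1 / (1 + exp(-v))
  bits <- as.integer(stats::runif(length(v)) < p)
  if (!any(bits == 1L)) bits[sample.int(length(bits), 1L)] <- 1L
  bits
}

# Deterministic surrogate accuracy of a mask: stratified internal CV with
# fold assignment derived from `seed` alone, so the same (mask, ds, seed)
# always scores identically.
#' Wrapper fitness of a feature mask
#'
#' Mean classification accuracy of the surrogate classifier over stratified
#' internal cross-validation folds, using only the columns selected by
#' `mask`. This is the objective the swarm maximizes. The default surrogate
#' is the probabilistic neural network (cheap, deterministic,
#' hyperparameter-light); `"ensemble"` scores masks with the full
#' three-member averaging ensemble at considerably higher cost.
#'
#' @param mask Logical or 0/1 vector over features with at least one set bit.
#' @param ds Normalized [labeled_dataset].
#' @param folds Internal fold count (default 3).
#' @param surrogate `"pnn"` (default) or `"ensemble"`.
#' @param seed Seed controlling the internal fold split.
#' @param sigma PNN spread (default 0.1 on \[0, 1\]-normalized data).
#' @return Accuracy in \[0, 1\].
#' @export
vpso_fitness <- function(mask, ds, folds = 3, surrogate = c("pnn", "ensemble"),
                         seed = 1, sigma = 0.1) {
  surrogate <- match.arg(surrogate)
  mask <- as.logical(mask)
  if (!any(mask)) err_validation("empty feature mask")
  fold <- stratified_folds(ds$y, folds, seed = seed)
  xs <- ds$x[, mask, drop = FALSE]
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    dtr <- labeled_dataset(xs[tr, , drop = FALSE], ds$y[tr],
                           class_names = ds$class_names,
                           positive_class = ds$positive_class)
    probs <- if (surrogate == "pnn") {
      fit <- fit_pnn(dtr, sigma = sigma)
      predict(fit, xs[!tr, , drop = FALSE], type = "prob")
    } else {
      fit_members_proba(dtr, xs[!tr, , drop = FALSE], seed = seed)
    }
    correct <- correct + sum(predict_label(probs) == ds$y[!tr])
  }
  correct / length(ds$y)
}

# (acc, -n_selected) lexicographic comparison: ties go to the smaller subset.
mask_better <- function(acc_a, n_a, acc_b, n_b) {
  acc_a > acc_b || (acc_a == acc_b && n_a < n_b)
}

#' Feature selection by velocity-equalized binary PSO
#'
#' Runs a swarm of binary particles over feature subsets. Each particle's
#' position is a bitmask; velocities follow the canonical update with a
#' linearly decaying inertia weight, then per-dimension velocity
#' equalization damps any component beyond `vmax` (see
#' [equalize_velocity()]). Positions are re-binarized through a sigmoid
#' transfer; fitness is the wrapper accuracy of [vpso_fitness()]. Fitness
#' ties between masks are broken toward fewer selected features.
#'
#' @param ds Normalized [labeled_dataset] with at least 2 features (with a
#'   single feature, selection is skipped and the full mask returned with a
#'   warning).
#' @param swarm_size Number of particles (default 20).
#' @param imax Iteration count (default 100).
#' @param c1,c2 Acceleration constants (default 2, 2).
#' @param wmax,wmin Inertia bounds (defaults 0.9, 0.5).
#' @param vmax Velocity cap (default 4).
#' @param alpha Equalization damping factor (default 0.5).
#' @param equalize Equalize velocities (default) or plain-clamp (classic
#'   binary PSO).
#' @param fitness_folds Internal CV folds for the fitness (default 3).
#' @param surrogate Fitness classifier, `"pnn"` (default) or `"ensemble"`.
#' @param sigma PNN spread for the fitness surrogate.
#' @param seed RNG seed; the full run is deterministic given the seed.
#' @return Object of class `vpso_selection`: `mask` (logical), `fitness`,
#'   `history` (gbest fitness per iteration, non-decreasing), `n_selected`,
#'   `feature_names` of the selected features, and `n_evaluated` distinct
#'   masks scored.
#' @export
vpso_select <- function(ds, swarm_size = 20, imax = 100, c1 = 2, c2 = 2,
                        wmax = 0.9, wmin = 0.5, vmax = 4, alpha = 0.5,
                        equalize = TRUE, fitness_folds = 3,
                        surrogate = c("pnn", "ensemble"), sigma = 0.1,
                        seed = 1) {
  surrogate <- match.arg(surrogate)
  n <- ncol(ds$x)
  if (n < 2L) {
    warning("fewer than 2 features; selection skipped, full mask returned")
    return(structure(list(mask = rep(TRUE, n), fitness = NA_real_,
                          history = numeric(0), n_selected = n,
                          feature_names = ds$feature_names,
                          n_evaluated = 0L),
                     class = "vpso_selection"))
  }
  if (swarm_size < 2L) err_config("swarm_size must be >= 2")
  if (wmin <= 0 || wmin > wmax || wmax > 1) {
    err_config("need 0 < wmin <= wmax <= 1")
  }

  cache <- new.env(parent = emptyenv())
  score <- function(bits) {
    key <- paste(bits, collapse = "")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    val <- vpso_fitness(bits, ds, folds = fitness_folds,
                        surrogate = surrogate, seed = seed, sigma = sigma)
    assign(key, val, envir = cache)
    val
  }

  with_seed(seed + 1L, {
    pos <- matrix(as.integer(stats::runif(swarm_size * n) < 0.5),
                  swarm_size, n)
    for (i in seq_len(swarm_size)) {     # repair empty subsets
      if (!any(pos[i, ] == 1L)) pos[i, sample.int(n, 1L)] <- 1L
    }
    vel <- matrix(stats::runif(swarm_size * n, -vmax, vmax), swarm_size, n)

    fit <- apply(pos, 1L, score)
    pbest <- pos
    pbest_fit <- fit
    gi <- 1L
    for (i in 2:swarm_size) {
      if (mask_better(pbest_fit[i], sum(pbest[i, ]),
                      pbest_fit[gi], sum(pbest[gi, ]))) gi <- i
    }
    gbest <- pbest[gi, ]
    gbest_fit <- pbest_fit[gi]

    history <- numeric(imax)
    for (iter in seq_len(imax)) {
      w <- inertia_weight(iter, imax, wmax, wmin)
      for (i in seq_len(swarm_size)) {
        vel[i, ] <- update_velocity(vel[i, ], pos[i, ], pbest[i, ], gbest,
                                    w = w, c1 = c1, c2 = c2, vmax = vmax,
                                    alpha = alpha, equalize = equalize)
        pos[i, ] <- binarize_position(vel[i, ])
        f <- score(pos[i, ])
        if (mask_better(f, sum(pos[i, ]), pbest_fit[i], sum(pbest[i, ]))) {
          pbest[i, ] <- pos[i, ]
          pbest_fit[i] <- f
        }
        if (mask_better(pbest_fit[i], sum(pbest[i, ]), gbest_fit, sum(gbest))) {
          gbest <- pbest[i, ]
          gbest_fit <- pbest_fit[i]
        }
      }
      history[iter] <- gbest_fit
    }
  })
  mask <- gbest == 1L
  structure(list(mask = mask, fitness = gbest_fit, history = history,
                 n_selected = sum(mask),
                 feature_names = ds$feature_names[mask],
                 n_evaluated = length(ls(cache))),
            class = "vpso_selection")
}

#' @export
print.vpso_selection <- function(x, ...) {
  cat(sprintf("VPSO selection: %d feature(s), fitness %.4f (%d masks evaluated)\n",
              x$n_selected, x$fitness, x$n_evaluated))
  cat("Selected:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}
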