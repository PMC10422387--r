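# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

asdmlc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "asdmlc_error", "error", "condition")))
}
err_config     <- function(msg) asdmlc_error(msg, "asdmlc_config_error")
err_validation <- function(msg) asdmlc_error(msg, "asdmlc_validation_error")
err_parse      <- function(msg) asdmlc_error(msg, "asdmlc_parse_error")

# Shannon entropy (base 2) of a count vector.
entropy2 <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Entropy (base 2) of each row of a count matrix, given row totals.
row_count_entropy <- function(counts, totals) {
  p <- counts / totals
  t <- p * log2(p)
  t[counts == 0] <- 0
  -rowSums(t)
}

# Row-wise log(sum(exp(x))) with max-subtraction for stability.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Squared Euclidean distances between rows of a and rows of b (n_a x n_b).
cross_sqdist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so class proportions are preserved per fold.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
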