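# Fixtures built in code; nothing is read from disk except files the
# helpers themselves write to tempdir().

# Min-max-normalized copy of a labeled dataset.
norm_ds <- function(ds) {
  labeled_dataset(transform_minmax(ds$x, fit_minmax(ds)), ds$y,
                  feature_names = ds$feature_names,
                  class_names = ds$class_names,
                  positive_class = ds$positive_class)
}

# 1-D fixture: minority at {0.0, 0.1}, majority at {0.9, 1.0, 1.1}.
fixture_1d <- function() {
  labeled_dataset(matrix(c(0.0, 0.1, 0.9, 1.0, 1.1), ncol = 1,
                         dimnames = list(NULL, "f1")),
                  c(1L, 1L, 0L, 0L, 0L),
                  class_names = c("neg", "pos"))
}

# Two well-separated Gaussian blobs (binary), centroids `sep` sd apart.
fixture_blobs <- function(n = 120, sep = 8, d = 2, ir = 1, seed = 42) {
  generate_synthetic(n_instances = n, n_features = d, n_informative = d,
                     imbalance_ratio = ir, class_separation = sep,
                     noise_sd = 1, seed = seed)
}

# A 4-row CSV file with a categorical target; returns the path.
tiny_csv <- function(dir = tempdir()) {
  path <- file.path(dir, "tiny.csv")
  writeLines(c("a,b,cls",
               "1.0,2.0,neg",
               "2.0,1.0,neg",
               "3.5,0.5,neg",
               "4.0,4.0,pos"), path)
  path
}

# The same 4 rows in KEEL .dat dialect; returns the path.
tiny_keel <- function(dir = tempdir()) {
  path <- file.path(dir, "tiny.dat")
  writeLines(c("@RELATION tiny",
               "@attribute a real [0.0, 5.0]",
               "@ATTRIBUTE b real [0.0, 5.0]",
               "@attribute cls {neg, pos}",
               "@inputs a, b",
               "@OUTPUTS cls",
               "@data",
               "1.0, 2.0, neg",
               "2.0, 1.0, neg",
               "3.5, 0.5, neg",
               "4.0, 4.0, pos"), path)
  path
}

# Independent squared-distance oracle (plain double loop).
cross_sqdist_ref <- function(a, b) {
  out <- matrix(NA_real_, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) out[i, j] <- sum((a[i, ] - b[j, ])^2)
  }
  out
}

# Brute-force exhaustive wrapper-selection optimum over all non-empty
# masks, using the same fitness and tie rule as the swarm.
exhaustive_best <- function(ds, seed, folds = 3) {
  n <- ncol(ds$x)
  best_acc <- -Inf
  best_n <- Inf
  for (code in 1:(2^n - 1)) {
    mask <- as.integer(intToBits(code)[1:n])
    acc <- vpso_fitness(mask, ds, folds = folds, seed = seed)
    if (acc > best_acc || (acc == best_acc && sum(mask) < best_n)) {
      best_acc <- acc
      best_n <- sum(mask)
    }
  }
  list(fitness = best_acc, n_selected = best_n)
}
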