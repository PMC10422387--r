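#' Construct a labeled dataset
#'
#' The container consumed and produced by every pipeline stage: a numeric
#' feature matrix plus integer class codes. Codes run from 0 to C-1 in order
#' of first appearance of the original labels; the minority (least frequent)
#' class is designated the positive class for binary metrics, since in the
#' clinical datasets this pipeline targets the minority class is the one of
#' interest.
#'
#' @param x Numeric matrix (or data frame of numerics), instances in rows.
#' @param y Class labels: factor, character, or integer codes in 0..C-1.
#' @param feature_names Column names; defaults to `colnames(x)` or `f1..fn`.
#' @param class_names Names for the class codes; derived from `y` when it is
#'   a factor/character vector.
#' @param positive_class Integer code of the positive class; defaults to the
#'   least frequent code (ties broken toward the lower code).
#' @return An object of class `labeled_dataset` with fields `x`, `y`,
#'   `feature_names`, `class_names`, `positive_class`.
#' @export
labeled_dataset <- function(x, y, feature_names = NULL, class_names = NULL,
                            positive_class = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    err_validation("features must form a numeric matrix")
  }
  if (nrow(x) != length(y)) {
    err_validation(sprintf("feature rows (%d) != number of labels (%d)",
                           nrow(x), length(y)))
  }
  if (anyNA(x)) err_validation("features contain missing values")
  if (anyNA(y)) err_validation("labels contain missing values")

  if (is.character(y) || is.factor(y)) {
    lev <- unique(as.character(y))       # order of first appearance
    codes <- match(as.character(y), lev) - 1L
    if (is.null(class_names)) class_names <- lev
    y <- codes
  } else {
    y <- as.integer(y)
    if (any(y < 0)) err_validation("integer labels must be codes >= 0")
    if (is.null(class_names)) class_names <- as.character(seq_len(max(y) + 1L) - 1L)
  }
  C <- length(class_names)
  if (C < 2L) err_validation("dataset must contain at least 2 classes")
  if (any(y >= C)) err_validation("label code out of range")

  feature_names <- feature_names %||% colnames(x) %||%
    paste0("f", seq_len(ncol(x)))
  colnames(x) <- feature_names

  if (is.null(positive_class)) {
    tab <- tabulate(y + 1L, nbins = C)
    positive_class <- which.min(tab) - 1L
  }
  structure(
    list(x = x, y = y, feature_names = feature_names,
         class_names = class_names, positive_class = as.integer(positive_class)),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled dataset: %d instances x %d features, %d classes\n",
              nrow(x$x), ncol(x$x), length(x$class_names)))
  tab <- tabulate(x$y + 1L, nbins = length(x$class_names))
  names(tab) <- x$class_names
  print(tab)
  cat(sprintf("Positive (minority) class: %s\n",
              x$class_names[x$positive_class + 1L]))
  invisible(x)
}

n_classes <- function(ds) length(ds$class_names)

#' Read a labeled dataset from CSV, ARFF, or KEEL format
#'
#' @param path File path.
#' @param format One of `"auto"`, `"csv"`, `"arff"`, `"keel"`. `"auto"` picks
#'   by extension (`.arff`, `.dat` for KEEL, otherwise CSV).
#' @param target Name of the class column. Defaults to the KEEL `@outputs`
#'   attribute when present, otherwise the last column.
#' @param impute `"none"` (default; missing values are rejected) or `"mean"`
#'   (impute feature columns with their mean).
#' @return A [labeled_dataset].
#' @export
read_table_data <- function(path, format = c("auto", "csv", "arff", "keel"),
                            target = NULL, impute = c("none", "mean")) {
  format <- match.arg(format)
  impute <- match.arg(impute)
  if (!file.exists(path)) err_config(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, arff = "arff", dat = "keel", "csv")
  }
  out <- switch(format,
    csv  = list(df = utils::read.csv(path, stringsAsFactors = FALSE),
                target = NULL),
    arff = list(df = foreign::read.arff(path), target = NULL),
    keel = read_keel(path))
  df <- out$df
  target <- target %||% out$target %||% names(df)[ncol(df)]
  if (!target %in% names(df)) {
    err_config(sprintf("target column '%s' not present in %s", target, path))
  }
  y <- df[[target]]
  feats <- df[setdiff(names(df), target)]
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(as.character(col)))
      bad <- which(is.na(num) & !is.na(col) &
                     trimws(as.character(col)) != "" &
                     !toupper(trimws(as.character(col))) %in% c("NA", "?"))
      if (length(bad)) {
        err_parse(sprintf("non-numeric value '%s' at row %d, column '%s'",
                          as.character(col)[bad[1]], bad[1], names(feats)[j]))
      }
      num[!is.na(col) & toupper(trimws(as.character(col))) %in% c("", "?")] <- NA
      feats[[j]] <- num
    }
  }
  X <- as.matrix(feats)
  if (anyNA(X)) {
    if (impute == "mean") {
      for (j in seq_len(ncol(X))) {
        nas <- is.na(X[, j])
        if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
      }
    } else {
      bad <- which(is.na(X), arr.ind = TRUE)[1, ]
      err_validation(sprintf(
        "missing value at row %d, column '%s' (use impute = 'mean' to impute)",
        bad[1], colnames(X)[bad[2]]))
    }
  }
  if (length(unique(as.character(y))) < 2L) {
    err_validation("target column has a single class; need at least 2")
  }
  ds <- labeled_dataset(X, as.character(y))
  attr(ds, "target") <- target
  ds
}

# KEEL .dat dialect: @relation ignored; @attribute/@inputs/@outputs/@data
# case-insensitive; comma-separated data rows.
read_keel <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  is_hdr <- startsWith(lines, "@")
  data_at <- which(toupper(sub("\\s.*$", "", lines)) == "@DATA")
  if (!length(data_at)) err_parse("KEEL file has no @data section")
  hdr <- lines[seq_len(data_at[1])][is_hdr[seq_len(data_at[1])]]
  kw <- toupper(sub("\\s.*$", "", hdr))
  attr_names <- vapply(hdr[kw == "@ATTRIBUTE"], function(l) {
    rest <- trimws(sub("^\\S+\\s+", "", l))
    sub("^([^\\s{\\[]+).*$", "\\1", rest, perl = TRUE)
  }, character(1), USE.NAMES = FALSE)
  if (!length(attr_names)) err_parse("KEEL file declares no @attribute lines")
  outputs <- hdr[kw == "@OUTPUTS"]
  target <- if (length(outputs)) {
    trimws(strsplit(sub("^\\S+\\s+", "", outputs[1]), ",")[[1]])[1]
  } else NULL
  body <- lines[(data_at[1] + 1L):length(lines)]
  body <- body[!startsWith(body, "@")]
  parts <- strsplit(body, ",")
  nc <- length(attr_names)
  ok <- lengths(parts) == nc
  if (!all(ok)) {
    err_parse(sprintf("KEEL data row %d has %d fields, expected %d",
                      which(!ok)[1], lengths(parts)[which(!ok)[1]], nc))
  }
  df <- as.data.frame(do.call(rbind, lapply(parts, trimws)),
                      stringsAsFactors = FALSE)
  names(df) <- attr_names
  list(df = df, target = target)
}

#' Write a labeled dataset to CSV
#'
#' Features are written at full double precision (15 significant digits) so
#' that a write/read round trip reproduces the matrix.
#'
#' @param ds A [labeled_dataset].
#' @param path Output path.
#' @param target Name for the class column (default `"class"`).
#' @export
write_csv_data <- function(ds, path, target = NULL) {
  target <- target %||% attr(ds, "target") %||% "class"
  df <- as.data.frame(ds$x)
  df[[target]] <- ds$class_names[ds$y + 1L]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Minority/majority class counts
#'
#' For binary data `ms` and `ml` are the minority and majority counts with
#' `ms <= ml` and `ms + ml = m`. For more than two classes the minority is
#' the least frequent class and `ml` aggregates all the rest; the result is
#' flagged `multiclass`.
#'
#' @param ds A [labeled_dataset].
#' @return An object of class `class_counts` with fields `ms`, `ml`, `m`,
#'   `minority` (class code) and `multiclass`.
#' @export
class_counts <- function(ds) {
  if (length(ds$y) == 0L) err_validation("empty dataset")
  C <- n_classes(ds)
  tab <- tabulate(ds$y + 1L, nbins = C)
  minority <- which.min(tab) - 1L
  ms <- tab[minority + 1L]
  structure(list(ms = as.integer(ms), ml = as.integer(sum(tab) - ms),
                 m = as.integer(sum(tab)), minority = minority,
                 multiclass = C > 2L),
            class = "class_counts")
}

#' @export
print.class_counts <- function(x, ...) {
  cat(sprintf("Class counts: minority ms=%d, majority ml=%d, total m=%d%s\n",
              x$ms, x$ml, x$m,
              if (x$multiclass) " (multiclass: ml aggregates all non-minority)" else ""))
  invisible(x)
}

#' Imbalance ratio (majority over minority)
#'
#' @param counts A `class_counts` object or a [labeled_dataset].
#' @return `ml / ms`, conventionally reported to 2 decimals in summaries.
#' @export
imbalance_ratio <- function(counts) {
  if (inherits(counts, "labeled_dataset")) counts <- class_counts(counts)
  if (counts$ms < 1L) err_validation("minority class is empty")
  counts$ml / counts$ms
}

#' Dataset profile summary
#'
#' Attribute count, instance count and imbalance ratio, the standard way
#' benchmark imbalanced datasets are tabulated.
#'
#' @param ds A [labeled_dataset].
#' @return Object of class `asdmlc_profile`.
#' @export
asdmlc_profile <- function(ds) {
  cc <- class_counts(ds)
  structure(list(n_features = ncol(ds$x), n_instances = nrow(ds$x),
                 class_table = stats::setNames(
                   tabulate(ds$y + 1L, nbins = n_classes(ds)), ds$class_names),
                 imbalance_ratio = imbalance_ratio(cc)),
            class = "asdmlc_profile")
}

#' @export
print.asdmlc_profile <- function(x, ...) {
  cat(sprintf("Attributes: %d\nExamples:   %d\nImbalance ratio: %.2f\n",
              x$n_features, x$n_instances, x$imbalance_ratio))
  print(x$class_table)
  invisible(x)
}
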