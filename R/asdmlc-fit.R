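# Internal: fit the three members on a training set and return the
# averaged probabilities for a test matrix (used by the "ensemble" fitness
# surrogate and by the main fit).
fit_members_proba <- function(dtr, xtest, seed = 1, pnn_sigma = 0.1,
                              cbdt_k = 3, anfis_epochs = 10, anfis_lr = 0.01,
                              anfis_max_inputs = 6) {
  models <- fit_members(dtr, seed = seed, pnn_sigma = pnn_sigma,
                        cbdt_k = cbdt_k, anfis_epochs = anfis_epochs,
                        anfis_lr = anfis_lr,
                        anfis_max_inputs = anfis_max_inputs)
  ensemble_average(lapply(models, function(mo) {
    member_proba(mo, xtest)
  }))
}

member_proba <- function(mo, xtest) {
  if (!is.null(mo$anfis_cols)) {
    predict(mo$model, xtest[, mo$anfis_cols, drop = FALSE], type = "prob")
  } else {
    predict(mo$model, xtest, type = "prob")
  }
}

fit_members <- function(dtr, seed = 1, pnn_sigma = 0.1, cbdt_k = 3,
                        anfis_epochs = 10, anfis_lr = 0.01,
                        anfis_max_inputs = 6) {
  # ANFIS rules grow as 2^inputs; if more features survive selection than
  # the cap, the ANFIS member sees the cap's worth of features ranked by
  # absolute correlation with the class label (other members see them all).
  n <- ncol(dtr$x)
  anfis_cols <- NULL
  dan <- dtr
  if (n > anfis_max_inputs) {
    sc <- abs(apply(dtr$x, 2L, function(col) {
      if (stats::sd(col) == 0) 0 else stats::cor(col, dtr$y)
    }))
    anfis_cols <- sort(order(sc, decreasing = TRUE)[seq_len(anfis_max_inputs)])
    dan <- labeled_dataset(dtr$x[, anfis_cols, drop = FALSE], dtr$y,
                           class_names = dtr$class_names,
                           positive_class = dtr$positive_class)
  }
  list(
    anfis = list(model = fit_anfis(dan, epochs = anfis_epochs, lr = anfis_lr,
                                   max_inputs = anfis_max_inputs),
                 anfis_cols = anfis_cols),
    pnn = list(model = fit_pnn(dtr, sigma = pnn_sigma), anfis_cols = NULL),
    cbdt = list(model = fit_cbdt(dtr, k = cbdt_k, seed = seed),
                anfis_cols = NULL))
}

#' Fit the full imbalance-aware ensemble pipeline
#'
#' Runs, on the training data only: (1) ADASYN oversampling of the minority
#' class (skipped when the degree of imbalance is already within
#' tolerance), (2) min-max normalization to \[0, 1\], (3) wrapper feature
#' selection by velocity-equalized binary PSO, and (4) fitting of the three
#' ensemble members — ANFIS, PNN and clustering-based decision trees — on
#' the selected columns. Prediction averages the members' class
#' probabilities.
#'
#' @param x A [labeled_dataset], or a formula (with `data`).
#' @param ... Passed on to methods.
#' @return Object of class `asdmlc` with the fitted stages.
#' @export
asdmlc <- function(x, ...) UseMethod("asdmlc")

#' @rdname asdmlc
#' @param formula Model formula `class ~ .` style; the response is the
#'   class column of `data`.
#' @param data Data frame holding features and the class column.
#' @export
asdmlc.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- mf[, -1L, drop = FALSE]
  asdmlc(labeled_dataset(as.matrix(X), y), ...)
}

#' @rdname asdmlc
#' @param oversample Run ADASYN (default TRUE). Required off for more than
#'   two classes.
#' @param select Run VPSO feature selection (default TRUE).
#' @param adasyn_k,beta,dth ADASYN neighbour count, balance level and
#'   imbalance tolerance (defaults 5, 1, 0.75).
#' @param adasyn_after_norm Normalize before oversampling instead of after
#'   (default FALSE: ADASYN operates on raw features).
#' @param norm_low,norm_high Normalization target range (defaults 0, 1).
#' @param vpso Named list of overrides for [vpso_select()] (e.g.
#'   `list(imax = 100)`); pipeline default uses `imax = 40`.
#' @param pnn_sigma PNN kernel spread (default 0.1).
#' @param cbdt_k Cluster count for the tree member (default 3).
#' @param anfis_epochs,anfis_lr ANFIS training epochs and learning rate in
#'   the pipeline (defaults 10, 0.01).
#' @param anfis_max_inputs Feature cap for the ANFIS member (default 6).
#' @param seed RNG seed; the whole fit is deterministic given the seed.
#' @export
asdmlc.labeled_dataset <- function(x, oversample = TRUE, select = TRUE,
                                   adasyn_k = 5, beta = 1, dth = 0.75,
                                   adasyn_after_norm = FALSE,
                                   norm_low = 0, norm_high = 1,
                                   vpso = list(), pnn_sigma = 0.1,
                                   cbdt_k = 3, anfis_epochs = 10,
                                   anfis_lr = 0.01, anfis_max_inputs = 6,
                                   seed = 1, ...) {
  ds <- x
  C <- n_classes(ds)
  if (oversample && C > 2L) {
    err_validation("ADASYN requires a binary dataset; refit with oversample = FALSE")
  }
  plan <- NULL
  norm <- NULL
  if (oversample && !adasyn_after_norm) {
    ov <- adasyn(ds, k = adasyn_k, beta = beta, dth = dth, seed = seed)
    ds <- ov$data
    plan <- ov$plan
  }
  norm <- fit_minmax(ds, low = norm_low, high = norm_high)
  ds <- labeled_dataset(transform_minmax(ds$x, norm), ds$y,
                        feature_names = ds$feature_names,
                        class_names = ds$class_names,
                        positive_class = ds$positive_class)
  if (oversample && adasyn_after_norm) {
    ov <- adasyn(ds, k = adasyn_k, beta = beta, dth = dth, seed = seed)
    ds <- ov$data
    plan <- ov$plan
  }
  selection <- NULL
  mask <- rep(TRUE, ncol(ds$x))
  if (select && ncol(ds$x) >= 2L) {
    vargs <- utils::modifyList(list(ds = ds, imax = 40, seed = seed), vpso)
    selection <- do.call(vpso_select, vargs)
    mask <- selection$mask
  }
  dsel <- labeled_dataset(ds$x[, mask, drop = FALSE], ds$y,
                          class_names = ds$class_names,
                          positive_class = ds$positive_class)
  members <- fit_members(dsel, seed = seed, pnn_sigma = pnn_sigma,
                         cbdt_k = cbdt_k, anfis_epochs = anfis_epochs,
                         anfis_lr = anfis_lr,
                         anfis_max_inputs = anfis_max_inputs)
  structure(list(members = members, norm = norm, mask = mask,
                 selection = selection, plan = plan,
                 feature_names = x$feature_names,
                 class_names = x$class_names,
                 positive_class = x$positive_class,
                 adasyn_after_norm = adasyn_after_norm,
                 seed = seed),
            class = "asdmlc")
}

#' Predict method for asdmlc models
#'
#' New data is min-max transformed with the training parameters, restricted
#' to the selected features, scored by each member, and the probabilities
#' averaged. Test data is never oversampled.
#'
#' @param object An `asdmlc` model.
#' @param newdata Numeric matrix or data frame of features (training
#'   columns, by name when available).
#' @param type `"prob"` (default) or `"class"`.
#' @param ... Unused.
#' @export
predict.asdmlc <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$x
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata))) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  xn <- transform_minmax(newdata, object$norm)
  xs <- xn[, object$mask, drop = FALSE]
  probs <- ensemble_average(lapply(object$members, member_proba, xtest = xs))
  colnames(probs) <- object$class_names
  if (type == "class") predict_label(probs) else probs
}

#' @export
print.asdmlc <- function(x, ...) {
  cat("ASDMLC ensemble fit\n")
  if (!is.null(x$plan)) {
    cat(sprintf("  ADASYN: d = %.3f, %d synthetic minority samples\n",
                x$plan$d, sum(x$plan$g)))
  } else cat("  ADASYN: off\n")
  cat(sprintf("  Features: %d of %d selected%s\n", sum(x$mask),
              length(x$mask),
              if (is.null(x$selection)) " (selection off)" else
                sprintf(" (VPSO fitness %.4f)", x$selection$fitness)))
  cat("  Members: ANFIS, PNN, clustering-based decision tree\n")
  invisible(x)
}

#' @export
summary.asdmlc <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) print(object$selection)
  if (!is.null(object$plan)) print(object$plan)
  invisible(object)
}
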