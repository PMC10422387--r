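# JSON serialization of fitted stage objects (versioned containers), so a
# model or audit plan can be re-applied exactly outside the fitting session.

SERIAL_VERSION <- "1"

to_serializable <- function(x) UseMethod("to_serializable")

#' @export
to_serializable.minmax_params <- function(x) {
  list(type = "minmax_params", version = SERIAL_VERSION,
       min = unname(x$min), max = unname(x$max), low = x$low, high = x$high,
       feature_names = x$feature_names)
}

#' @export
to_serializable.pnn <- function(x) {
  list(type = "pnn", version = SERIAL_VERSION, x = x$x, y = x$y,
       sigma = x$sigma, priors = x$priors, class_names = x$class_names,
       positive_class = x$positive_class)
}

#' @export
to_serializable.anfis <- function(x) {
  list(type = "anfis", version = SERIAL_VERSION,
       heads = lapply(x$heads, function(h) {
         list(centers = h$prem$centers, sigmas = h$prem$sigmas,
              rules = h$rules, theta = h$theta)
       }),
       n_inputs = x$n_inputs, n_mf = x$n_mf, class_names = x$class_names,
       positive_class = x$positive_class)
}

#' @export
to_serializable.cbdt <- function(x) {
  list(type = "cbdt", version = SERIAL_VERSION, centers = x$centers,
       trees = x$trees, k = x$k, class_names = x$class_names,
       positive_class = x$positive_class)
}

#' @export
to_serializable.adasyn_plan <- function(x) {
  list(type = "adasyn_plan", version = SERIAL_VERSION, d = x$d, G = x$G,
       delta = x$delta, r = x$r, r_hat = x$r_hat, g = x$g,
       parents = x$parents, lambda = x$lambda, minority = x$minority)
}

#' @export
to_serializable.vpso_selection <- function(x) {
  list(type = "vpso_selection", version = SERIAL_VERSION,
       mask = as.integer(x$mask), fitness = x$fitness, history = x$history,
       n_selected = x$n_selected, feature_names = x$feature_names)
}

#' Write a fitted stage object to JSON
#'
#' Supports min-max parameters, PNN, ANFIS and clustering-tree models, the
#' ADASYN audit plan, and a feature-selection result. Models written this
#' way reload with [read_model_json()] and predict identically.
#'
#' @param x Object to serialize.
#' @param path Output path.
#' @export
write_model_json <- function(x, path) {
  jsonlite::write_json(to_serializable(x), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

relist_tree <- function(node) {
  if (isTRUE(node$leaf)) {
    list(leaf = TRUE, counts = as.numeric(unlist(node$counts)))
  } else {
    list(leaf = FALSE, j = node$j[[1]], thr = node$thr[[1]],
         left = relist_tree(node$left), right = relist_tree(node$right))
  }
}

relist_matrix <- function(rows) {
  do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
}

#' Reload a stage object written by [write_model_json()]
#'
#' @param path JSON path.
#' @return The reconstructed object with its original class.
#' @export
read_model_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  switch(o$type,
    minmax_params = structure(
      list(min = num(o$min), max = num(o$max), low = o$low, high = o$high,
           feature_names = if (length(o$feature_names)) chr(o$feature_names)),
      class = "minmax_params"),
    pnn = structure(
      list(x = relist_matrix(o$x), y = as.integer(unlist(o$y)),
           sigma = o$sigma, priors = num(o$priors),
           class_names = chr(o$class_names),
           positive_class = o$positive_class),
      class = "pnn"),
    anfis = structure(
      list(heads = lapply(o$heads, function(h) {
             list(prem = list(centers = lapply(h$centers, num),
                              sigmas = lapply(h$sigmas, num)),
                  rules = relist_matrix(h$rules), theta = num(h$theta))
           }),
           n_inputs = o$n_inputs, n_mf = o$n_mf,
           class_names = chr(o$class_names),
           positive_class = o$positive_class),
      class = "anfis"),
    cbdt = structure(
      list(centers = relist_matrix(o$centers),
           trees = lapply(o$trees, relist_tree),
           k = o$k, class_names = chr(o$class_names),
           positive_class = o$positive_class),
      class = "cbdt"),
    adasyn_plan = structure(
      list(d = o$d, G = o$G, delta = as.integer(unlist(o$delta)),
           r = num(o$r), r_hat = num(o$r_hat),
           g = as.integer(unlist(o$g)),
           parents = if (length(o$parents)) relist_matrix(o$parents)
                     else matrix(integer(0), 0, 2),
           lambda = num(o$lambda), minority = o$minority),
      class = "adasyn_plan"),
    vpso_selection = structure(
      list(mask = unlist(o$mask) == 1, fitness = o$fitness,
           history = num(o$history), n_selected = o$n_selected,
           feature_names = chr(o$feature_names)),
      class = "vpso_selection"),
    err_parse(sprintf("unknown serialized type '%s'", o$type)))
}
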