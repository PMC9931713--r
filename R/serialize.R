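#' Serialize / restore a reservoir model
#'
#' Stores the grid dimensions, input mapping, sparse weight triplets and
#' all parameters in a versioned single-file JSON archive.  Numbers are
#' written at full precision so the round trip is lossless.
#'
#' @param model an `snn_reservoir`.
#' @param path file path (conventionally `.json`).
#' @return `read_model` returns the restored `snn_reservoir`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "snn_reservoir"))
  obj <- list(
    format = "longsnn-reservoir",
    version = 1L,
    grid_dims = model$grid$dims,
    params = unclass(model$params),
    init_seed = model$init_seed,
    input_mapping = if (is.null(model$input_mapping)) NULL else
      as.integer(model$input_mapping),
    connections = list(pre = model$pre, post = model$post,
                       # 17 significant digits: doubles survive the text
                       # round trip bit-exactly
                       weight = sprintf("%.17g", model$weight))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Serialize / restore a fitted deSNN classifier
#'
#' Stores the output-neuron weight matrix, labels, source subjects and
#' readout parameters in a versioned JSON archive (weights at full
#' precision, so the round trip is lossless).
#'
#' @param classifier a fitted `desnn_classifier`.
#' @param path file path.
#' @return `read_classifier` returns the restored classifier.
#' @export
write_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "desnn_classifier"))
  obj <- list(
    format = "longsnn-desnn",
    version = 1L,
    params = unclass(classifier$params),
    labels = classifier$labels,
    source_subject = classifier$source_subject,
    n_neurons = ncol(classifier$weights),
    weights = sprintf("%.17g", as.vector(classifier$weights))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "longsnn-desnn")
    stop("not a longsnn deSNN classifier archive")
  if (obj$version != 1) stop("unsupported archive version ", obj$version)
  w <- matrix(as.numeric(obj$weights), ncol = obj$n_neurons)
  structure(
    list(weights = w, labels = obj$labels,
         source_subject = obj$source_subject,
         params = do.call(desnn_params, obj$params)),
    class = "desnn_classifier"
  )
}

#' Export per-subject predictions
#'
#' Writes `subject_id,true_label,predicted_label,distance` rows.
#'
#' @param predictions data.frame from [classify_desnn()] (columns
#'   `predicted_label`, `distance`).
#' @param subject_id subject identifiers.
#' @param true_label known labels.
#' @param path CSV path.
#' @export
write_predictions <- function(predictions, subject_id, true_label, path) {
  out <- data.frame(subject_id = subject_id,
                    true_label = as.character(true_label),
                    predicted_label = predictions$predicted_label,
                    distance = sprintf("%.17g", predictions$distance))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "longsnn-reservoir")
    stop("not a longsnn reservoir archive")
  if (obj$version != 1) stop("unsupported archive version ", obj$version)
  params <- do.call(reservoir_params, obj$params)
  model <- structure(
    list(grid = neuron_grid(obj$grid_dims),
         pre = as.integer(obj$connections$pre),
         post = as.integer(obj$connections$post),
         weight = as.numeric(obj$connections$weight),
         input_mapping = if (length(obj$input_mapping))
           as.integer(obj$input_mapping) else NULL,
         params = params,
         init_seed = obj$init_seed),
    class = "snn_reservoir"
  )
  model
}
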