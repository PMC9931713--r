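#' deSNN readout parameters
#'
#' @param mod rank-order modulation factor in `(0, 1)`; the i-th neuron to
#'   fire (0-based rank r) starts with weight `mod^r`.  Default 0.8.
#' @param drift per-step weight drift after a neuron's first spike
#'   (up when it fires, down otherwise, floored at 0).  Default 0.005.
#' @param k_neighbors number of nearest output neurons voting at
#'   prediction time.  Default 1.
#' @return object of class `desnn_params`.
#' @export
desnn_params <- function(mod = 0.8, drift = 0.005, k_neighbors = 1) {
  stopifnot(mod > 0, mod < 1, drift >= 0, k_neighbors >= 1)
  structure(list(mod = mod, drift = drift,
                 k_neighbors = as.integer(k_neighbors)),
            class = "desnn_params")
}

#' deSNN weight vector of one raster
#'
#' Rank-order coding over first-spike times (ties by neuron id) gives the
#' initial weights `mod^rank`; afterwards each neuron's weight drifts up by
#' `drift` on steps where it fires and down (floored at 0) where it does
#' not.  Neurons that never fire have weight 0.
#'
#' @param raster integer matrix time steps x neurons (a `spike_raster`).
#' @param params [desnn_params()].
#' @return numeric weight vector, one entry per reservoir neuron.
#' @export
desnn_weight_vector <- function(raster, params = desnn_params()) {
  raster <- unclass(raster)
  storage.mode(raster) <- "integer"
  desnn_weights_cpp(raster, params$mod, params$drift)
}

#' deSNN weight vectors for a set of subjects
#'
#' Propagates each subject's spike train through the frozen reservoir and
#' summarises the resulting raster with the rank-order + drift rule, in one
#' batched pass (no rasters are materialised).
#'
#' @param model mapped, frozen `snn_reservoir`.
#' @param sts `spike_trains` over the subjects.
#' @param params [desnn_params()].
#' @return numeric matrix subjects x reservoir neurons.
#' @export
desnn_matrix <- function(model, sts, params = desnn_params()) {
  stopifnot(inherits(sts, "spike_trains"))
  dm <- dim(sts$spikes)
  check_mapped(model, dm[2])
  sp <- sts$spikes
  storage.mode(sp) <- "integer"
  W <- lif_desnn_batch_cpp(model$grid$n_neurons,
                           model$pre - 1L, model$post - 1L, model$weight,
                           model$input_mapping - 1L, sp,
                           dm[1], dm[2], dm[3],
                           model$params$leak, model$params$firing_threshold,
                           model$params$refractory_steps,
                           params$mod, params$drift)
  rownames(W) <- sts$subject_id
  W
}

#' Fit the deSNN output layer
#'
#' Creates one output neuron per training subject: the subject's spike
#' train is propagated through the frozen (already STDP-trained) reservoir
#' and the resulting raster is summarised into a rank-order + drift weight
#' vector which, together with the subject's class label, constitutes the
#' output neuron.  The reservoir is not adapted during this supervised
#' phase.
#'
#' @param x either a `spike_trains` object over the training subjects
#'   (requires `model`) or a list of precomputed `spike_raster` matrices.
#' @param labels factor/character class label per training subject.
#' @param params [desnn_params()].
#' @param model the frozen, mapped `snn_reservoir` (needed when `x` is a
#'   `spike_trains`).
#' @return object of class `desnn_classifier`.
#' @export
fit_desnn <- function(x, labels, params = desnn_params(), model = NULL) {
  if (inherits(x, "spike_trains")) {
    if (is.null(model)) stop("model is required when fitting from spike trains")
    W <- desnn_matrix(model, x, params)
    ids <- x$subject_id
  } else if (is.list(x)) {
    W <- do.call(rbind, lapply(x, desnn_weight_vector, params = params))
    ids <- if (!is.null(names(x))) names(x) else as.character(seq_len(length(x)))
  } else stop("x must be spike_trains or a list of rasters")

  labels <- as.character(labels)
  if (length(labels) != nrow(W)) stop("one label per training subject required")
  empty <- rowSums(W != 0) == 0
  if (any(empty))
    warning(sum(empty), " training subject(s) produced no reservoir spikes; ",
            "their output neurons are all-zero")
  structure(
    list(weights = W, labels = labels,
         source_subject = ids, params = params),
    class = "desnn_classifier"
  )
}

#' @export
print.desnn_classifier <- function(x, ...) {
  cat("desnn_classifier:", nrow(x$weights), "output neurons,",
      length(unique(x$labels)), "classes,", ncol(x$weights),
      "reservoir neurons\n")
  invisible(x)
}

#' Classify a test subject
#'
#' The test raster (propagated through the same frozen reservoir) is
#' summarised with the identical rank-order + drift rule and labelled by
#' its k nearest output neurons in Euclidean distance (majority vote; ties
#' broken by smallest distance sum, then lexicographically).
#'
#' @param object a fitted `desnn_classifier`.
#' @param raster test subject's `spike_raster` (or a list of rasters).
#' @param ... unused.
#' @return for one raster, a list with `label` and `distance`; for a list
#'   of rasters, a data.frame `predicted_label`, `distance`.
#' @export
predict.desnn_classifier <- function(object, raster, ...) {
  if (is.list(raster) && !is.matrix(raster)) {
    res <- lapply(raster, function(r) predict(object, r))
    return(data.frame(
      predicted_label = vapply(res, `[[`, character(1), "label"),
      distance = vapply(res, `[[`, numeric(1), "distance")))
  }
  w <- desnn_weight_vector(raster, object$params)
  res <- classify_desnn(object, matrix(w, nrow = 1))
  list(label = res$predicted_label[1], distance = res$distance[1])
}

#' Classify precomputed deSNN weight vectors
#'
#' @param object fitted `desnn_classifier`.
#' @param W matrix of test weight vectors (subjects x reservoir neurons),
#'   e.g. from [desnn_matrix()].
#' @return data.frame `predicted_label`, `distance`.
#' @export
classify_desnn <- function(object, W) {
  stopifnot(inherits(object, "desnn_classifier"),
            ncol(W) == ncol(object$weights))
  Wtr <- object$weights
  d2 <- outer(rowSums(Wtr^2), rowSums(W^2), "+") - 2 * Wtr %*% t(W)
  d2[d2 < 0] <- 0  # numerical guard
  D <- sqrt(d2)  # train x test
  k <- min(object$params$k_neighbors, nrow(Wtr))
  lab <- character(ncol(D)); dist <- numeric(ncol(D))
  for (i in seq_len(ncol(D))) {
    d <- D[, i]
    nn <- order(d)[seq_len(k)]
    votes <- table(object$labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      dsum <- vapply(top, function(lb) sum(d[nn][object$labels[nn] == lb]),
                     numeric(1))
      top <- sort(top[dsum == min(dsum)])[1]
    }
    lab[i] <- top
    dist[i] <- min(d[nn][object$labels[nn] == top])
  }
  data.frame(predicted_label = lab, distance = dist,
             stringsAsFactors = FALSE)
}
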