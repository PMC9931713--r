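#' Cluster reservoir neurons around the input variables
#'
#' Every neuron is assigned to the variable whose input neuron is nearest
#' in Euclidean distance; ties are broken by the strongest absolute direct
#' connection weight to the tied input neurons (either direction), then by
#' the lowest variable id.  The partition is deterministic and every input
#' neuron belongs to its own variable's cluster.
#'
#' @param model mapped `snn_reservoir`.
#' @return integer vector: neuron id -> variable id.
#' @export
cluster_neurons <- function(model) {
  stopifnot(inherits(model, "snn_reservoir"))
  if (is.null(model$input_mapping)) stop("model has no input mapping")
  co <- model$grid$coords
  inputs <- model$input_mapping
  V <- length(inputs)
  # distances neuron x input site
  D <- matrix(0, nrow = model$grid$n_neurons, ncol = V)
  for (v in seq_len(V))
    D[, v] <- sqrt(rowSums(sweep(co, 2, co[inputs[v], ])^2))
  mind <- do.call(pmin, as.data.frame(D))
  assign <- integer(model$grid$n_neurons)
  for (i in seq_len(model$grid$n_neurons)) {
    tied <- which(D[i, ] == mind[i])
    if (length(tied) == 1) {
      assign[i] <- tied
    } else {
      # strongest |direct connection| between neuron i and tied input neurons
      strength <- vapply(tied, function(v) {
        inp <- inputs[v]
        k <- (model$pre == i & model$post == inp) |
          (model$pre == inp & model$post == i)
        if (any(k)) max(abs(model$weight[k])) else 0
      }, numeric(1))
      tied <- tied[strength == max(strength)]
      assign[i] <- min(tied)
    }
  }
  assign
}

#' Feature interaction network from a spike log
#'
#' Aggregates the transmission events of STDP learning into a variables x
#' variables count matrix: every spike transmitted over a connection j -> i
#' increments the cell (cluster(j), cluster(i)).  The directed matrix
#' conserves the total transmission count exactly (including the diagonal
#' of intra-cluster transmissions); [fin_symmetric()] gives the undirected
#' view used for plotting.
#'
#' @param log `spike_log` from [train_stdp()] on the same model.
#' @param clusters neuron -> variable assignment from [cluster_neurons()].
#' @param group_label optional label carried in the result.
#' @return object of class `fin`: list with directed `counts` (V x V),
#'   `total` and `group_label`.
#' @export
compute_fin <- function(log, clusters, group_label = NA_character_) {
  stopifnot(inherits(log, "spike_log"))
  if (length(clusters) < max(c(log$pre, log$post, 0)))
    stop("cluster assignment does not cover the model's neurons")
  V <- max(clusters)
  counts <- matrix(0, V, V)
  cp <- clusters[log$pre]
  cq <- clusters[log$post]
  for (k in seq_along(log$trans_counts)) {
    if (log$trans_counts[k] > 0)
      counts[cp[k], cq[k]] <- counts[cp[k], cq[k]] + log$trans_counts[k]
  }
  structure(list(counts = counts, total = sum(counts),
                 group_label = group_label),
            class = "fin")
}

#' @export
print.fin <- function(x, ...) {
  cat("fin:", nrow(x$counts), "x", ncol(x$counts), "clusters,",
      x$total, "transmitted spikes",
      if (!is.na(x$group_label)) paste0("(", x$group_label, ")"), "\n")
  invisible(x)
}

#' Symmetrized (undirected) interaction matrix
#'
#' @param fin a `fin` object.
#' @return V x V symmetric matrix `counts + t(counts)`.
#' @export
fin_symmetric <- function(fin) {
  stopifnot(inherits(fin, "fin"))
  fin$counts + t(fin$counts)
}

#' Export a feature interaction network
#'
#' Writes the symmetrized V x V matrix (`fin_<group>.csv` style) and the
#' upper-triangle edge list.
#'
#' @param fin a `fin` object.
#' @param matrix_path CSV path for the symmetrized matrix.
#' @param edges_path optional CSV path for the edge list
#'   (`variable_a,variable_b,count`).
#' @export
write_fin <- function(fin, matrix_path, edges_path = NULL) {
  sym <- fin_symmetric(fin)
  V <- nrow(sym)
  dimnames(sym) <- list(seq_len(V), seq_len(V))
  write.csv(sym, matrix_path, row.names = TRUE, quote = FALSE)
  if (!is.null(edges_path)) {
    idx <- which(upper.tri(sym, diag = TRUE), arr.ind = TRUE)
    edges <- data.frame(variable_a = idx[, 1], variable_b = idx[, 2],
                        count = sym[idx])
    edges <- edges[order(edges$variable_a, edges$variable_b), , drop = FALSE]
    write.csv(edges, edges_path, row.names = FALSE, quote = FALSE)
  }
  invisible(matrix_path)
}

#' Compare per-group trained models
#'
#' Tabulates, for each group's reservoir, the global mean absolute
#' connection weight `W_a`, the per-variable weight means, and the total
#' feature-interaction mass (sum of all directed FIN counts).  The group
#' ordering of these quantities is the headline interaction statistic.
#'
#' @param bundle named list per group with elements `model`, `log`, `fin`
#'   (as produced by [run_group_visualization()]).
#' @return list with data.frames `summary` (group, W_a, fin_total,
#'   total_spikes) and `per_variable` (group, variable_id,
#'   mean_abs_weight).
#' @export
compare_groups <- function(bundle) {
  stopifnot(length(bundle) >= 1, !is.null(names(bundle)))
  rows <- list(); pv <- list()
  for (g in names(bundle)) {
    b <- bundle[[g]]
    s <- summarize_connectivity(b$model)
    rows[[g]] <- data.frame(group = g, W_a = s$W_a,
                            fin_total = b$fin$total,
                            stringsAsFactors = FALSE)
    pvg <- s$per_variable
    pvg$group <- g
    pv[[g]] <- pvg[, c("group", "variable_id", "mean_abs_weight")]
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       per_variable = do.call(rbind, c(pv, list(make.row.names = FALSE))))
}
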