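#' 3D neuron grid
#'
#' @param dims integer vector `(nx, ny, nz)`; the default 10 x 10 x 10 gives
#'   the 1000-neuron cube the analysis uses.
#' @return object of class `neuron_grid` with a `coords` matrix (neurons x
#'   3, integer coordinates starting at 1; neuron ids are row indices).
#' @export
neuron_grid <- function(dims = c(10, 10, 10)) {
  stopifnot(length(dims) == 3, all(dims >= 1))
  dims <- as.integer(dims)
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                  z = seq_len(dims[3])))
  structure(list(dims = dims, coords = coords, n_neurons = prod(dims)),
            class = "neuron_grid")
}

#' Reservoir parameters
#'
#' @param connection_radius maximum Euclidean distance (in neuron-grid
#'   units) between connected neurons; default 2.
#' @param firing_threshold membrane potential at which a neuron fires;
#'   default 0.50.
#' @param leak multiplicative membrane potential retention per step in
#'   `[0, 1)`; default 0.1.  Time steps represent roughly one month of
#'   real time, so potentials are mostly forgotten between steps and
#'   reservoir activity is input-driven rather than self-sustained.
#' @param refractory_steps steps a neuron stays silent after firing;
#'   default 0 (no refractoriness at the monthly time resolution).
#' @param inhibitory_fraction probability a connection is negative
#'   (inhibitory); default 0.2.
#' @param stdp_rate additive STDP learning rate; default 0.01.
#' @param p0 base connection probability; a pair at distance d connects
#'   with probability `min(1, p0 / d)`; default 0.15.
#' @param w0 initial weight scale; magnitudes are drawn `Uniform(0, w0) / d`;
#'   default 0.8.
#' @return object of class `reservoir_params`.
#' @export
reservoir_params <- function(connection_radius = 2, firing_threshold = 0.50,
                             leak = 0.1, refractory_steps = 0,
                             inhibitory_fraction = 0.2, stdp_rate = 0.01,
                             p0 = 0.15, w0 = 0.8) {
  stopifnot(connection_radius > 0, firing_threshold > 0,
            leak >= 0, leak < 1, refractory_steps >= 0,
            inhibitory_fraction >= 0, inhibitory_fraction < 1,
            stdp_rate >= 0, p0 > 0, w0 > 0)
  structure(list(connection_radius = connection_radius,
                 firing_threshold = firing_threshold, leak = leak,
                 refractory_steps = as.integer(refractory_steps),
                 inhibitory_fraction = inhibitory_fraction,
                 stdp_rate = stdp_rate, p0 = p0, w0 = w0),
            class = "reservoir_params")
}

#' Initialise a small-world reservoir
#'
#' Every ordered pair of distinct neurons within `connection_radius`
#' (Euclidean distance d) is connected with probability `min(1, p0 / d)`;
#' connection magnitudes are drawn `Uniform(0, w0) / d` and the sign is
#' negative with probability `inhibitory_fraction`.  Nearby neurons are thus
#' both more likely to connect and more strongly connected — the standard
#' small-world recipe for 3D spiking reservoirs.
#'
#' @param grid a [neuron_grid()].
#' @param params a [reservoir_params()].
#' @param seed integer seed; the same seed reproduces the weight map
#'   exactly.
#' @return object of class `snn_reservoir` (unmapped: no input assignment
#'   yet) with connection triplets `pre`, `post`, `weight`.
#' @export
init_small_world <- function(grid, params = reservoir_params(), seed = 1) {
  stopifnot(inherits(grid, "neuron_grid"), inherits(params, "reservoir_params"))
  pairs <- radius_pairs(grid, params$connection_radius)
  with_seed(seed, {
    keep <- stats::runif(nrow(pairs)) < pmin(1, params$p0 / pairs[, "dist"])
    pairs <- pairs[keep, , drop = FALSE]
    d <- pairs[, "dist"]
    mag <- stats::runif(nrow(pairs), 0, params$w0) / d
    sign <- ifelse(stats::runif(nrow(pairs)) < params$inhibitory_fraction, -1, 1)
    structure(
      list(grid = grid,
           pre = as.integer(pairs[, "pre"]), post = as.integer(pairs[, "post"]),
           weight = mag * sign,
           input_mapping = NULL, params = params, init_seed = as.integer(seed)),
      class = "snn_reservoir"
    )
  })
}

# all ordered pairs (pre, post), pre != post, within Euclidean radius
radius_pairs <- function(grid, radius) {
  co <- grid$coords
  n <- grid$n_neurons
  # candidate integer offsets within the radius
  r <- floor(radius)
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  d2 <- rowSums(off^2)
  off <- off[d2 > 0 & d2 <= radius^2, , drop = FALSE]
  if (nrow(off) == 0)
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("pre", "post", "dist", "d2"))))
  dims <- grid$dims
  res <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    tx <- co[, 1] + off[k, 1]; ty <- co[, 2] + off[k, 2]; tz <- co[, 3] + off[k, 3]
    ok <- tx >= 1 & tx <= dims[1] & ty >= 1 & ty <= dims[2] & tz >= 1 & tz <= dims[3]
    post <- (tz[ok] - 1) * dims[1] * dims[2] + (ty[ok] - 1) * dims[1] + tx[ok]
    res[[k]] <- cbind(pre = which(ok), post = post,
                      dist = sqrt(sum(off[k, ]^2)), d2 = sum(off[k, ]^2))
  }
  out <- do.call(rbind, res)
  out[order(out[, "pre"], out[, "post"]), , drop = FALSE]
}

#' @export
print.snn_reservoir <- function(x, ...) {
  cat("snn_reservoir:", x$grid$n_neurons, "neurons,",
      length(x$pre), "connections,",
      if (is.null(x$input_mapping)) "unmapped" else
        paste(length(x$input_mapping), "inputs mapped"), "\n")
  invisible(x)
}

#' Deterministic input-site coordinates by farthest-point sampling
#'
#' Chooses `n` well-spread neuron positions for the input variables: start
#' at the grid corner, then repeatedly add the neuron maximising the minimum
#' distance to the sites chosen so far (ties broken by lowest neuron id).
#'
#' @param grid a [neuron_grid()].
#' @param n number of input sites (23 for the shipped catalogue).
#' @return integer vector of `n` distinct neuron ids.
#' @export
input_sites <- function(grid, n = 23) {
  stopifnot(inherits(grid, "neuron_grid"), n >= 1, n <= grid$n_neurons)
  co <- grid$coords
  sites <- 1L  # corner (1,1,1)
  mind <- sqrt(rowSums(sweep(co, 2, co[1, ])^2))
  while (length(sites) < n) {
    nxt <- which.max(mind)  # first max = lowest id on ties
    sites <- c(sites, nxt)
    mind <- pmin(mind, sqrt(rowSums(sweep(co, 2, co[nxt, ])^2)))
  }
  sites
}

#' Attach an input mapping to a reservoir
#'
#' @param model an `snn_reservoir`.
#' @param mapping named integer vector variable id -> neuron id, injective.
#' @return mapped `snn_reservoir`.
#' @export
set_input_mapping <- function(model, mapping) {
  stopifnot(inherits(model, "snn_reservoir"))
  mapping <- as.integer(mapping)
  if (anyDuplicated(mapping)) stop("input mapping must be injective")
  if (any(mapping < 1 | mapping > model$grid$n_neurons))
    stop("input mapping refers to neurons outside the grid")
  model$input_mapping <- mapping
  model
}

#' Simulate LIF dynamics for one subject (frozen weights)
#'
#' Drives the reservoir with one subject's signed spike train.  Membrane
#' update: `u_i(t) = leak * u_i(t-1) + sum_j W_ji * s_j(t-1) + I_i(t)`,
#' where `I` injects the subject's +/-1 input spikes at the mapped input
#' neurons; a neuron fires at `u >= firing_threshold`, resets to 0, and is
#' refractory for `refractory_steps`.  Weights are not adapted.
#'
#' @param model mapped `snn_reservoir`.
#' @param spikes integer matrix time steps x variables in `{-1,0,+1}` (one
#'   subject), or a `spike_trains` object with exactly one subject.
#' @return integer raster matrix (time steps x neurons) of class
#'   `spike_raster`.
#' @export
simulate_lif <- function(model, spikes) {
  sp <- as_subject_spikes(spikes)
  check_mapped(model, ncol(sp))
  res <- lif_run_cpp(model$grid$n_neurons,
                     model$pre - 1L, model$post - 1L, model$weight,
                     model$input_mapping - 1L, sp,
                     model$params$leak, model$params$firing_threshold,
                     model$params$refractory_steps,
                     0, TRUE, FALSE)
  structure(res$raster, class = c("spike_raster", "matrix"))
}

as_subject_spikes <- function(spikes) {
  if (inherits(spikes, "spike_trains")) {
    if (dim(spikes$spikes)[1] != 1)
      stop("pass a single subject's spike train")
    sp <- spikes$spikes[1, , ]
    return(t(sp))  # time x variables
  }
  storage.mode(spikes) <- "integer"
  spikes
}

check_mapped <- function(model, n_vars) {
  if (is.null(model$input_mapping))
    stop("reservoir has no input mapping; call set_input_mapping() first")
  if (length(model$input_mapping) != n_vars)
    stop("spike train has ", n_vars, " variables but mapping has ",
         length(model$input_mapping))
  invisible(TRUE)
}

#' Unsupervised STDP training over a set of subjects
#'
#' Presents subjects sequentially (in a seeded order) and adapts connection
#' magnitudes with additive nearest-step STDP: a connection is potentiated
#' by `stdp_rate` when its presynaptic neuron fired one step before the
#' postsynaptic one, and depressed by `stdp_rate` (magnitude floored at 0)
#' in the reverse order.  Connection topology and signs never change.  The
#' returned spike log records, per connection, how many spikes it
#' transmitted (presynaptic neuron fired on the previous step), which is
#' what the feature interaction network counts.
#'
#' @param model mapped `snn_reservoir`.
#' @param sts `spike_trains` over the training subjects.
#' @param passes number of presentation passes over the subjects (default 1).
#' @param order_seed seed for the subject presentation order.
#' @param record_events if `TRUE`, also keep the individual transmission
#'   events (`step`, `pre`, `post`, `subject`); memory-hungry, intended for
#'   small runs and audits.
#' @return list with `model` (trained reservoir) and `log` (class
#'   `spike_log`: per-connection transmission counts, total count, optional
#'   event table).
#' @export
train_stdp <- function(model, sts, passes = 1, order_seed = 1,
                       record_events = FALSE) {
  stopifnot(inherits(sts, "spike_trains"))
  n_sub <- dim(sts$spikes)[1]
  check_mapped(model, dim(sts$spikes)[2])
  order <- with_seed(order_seed, {
    as.vector(replicate(passes, sample.int(n_sub)))
  })
  trans <- numeric(length(model$pre))
  events <- list()
  weight <- model$weight
  for (i in seq_along(order)) {
    s <- order[i]
    sp <- t(sts$spikes[s, , ])
    res <- lif_run_cpp(model$grid$n_neurons,
                       model$pre - 1L, model$post - 1L, weight,
                       model$input_mapping - 1L, sp,
                       model$params$leak, model$params$firing_threshold,
                       model$params$refractory_steps,
                       model$params$stdp_rate, FALSE, record_events)
    weight <- res$weights
    trans <- trans + res$trans_counts
    if (record_events && nrow(res$events) > 0) {
      ev <- as.data.frame(res$events)
      names(ev) <- c("step", "pre", "post")
      ev$subject <- sts$subject_id[s]
      events[[length(events) + 1]] <- ev
    }
  }
  model$weight <- weight
  log <- structure(
    list(pre = model$pre, post = model$post, trans_counts = trans,
         total = sum(trans),
         events = if (record_events) do.call(rbind, events) else NULL),
    class = "spike_log"
  )
  list(model = model, log = log)
}

#' Connection-weight summary of a reservoir
#'
#' `W_a` is the mean absolute weight over existing connections — the single
#' connectivity metric reported per trained model.  The per-variable
#' breakdown averages absolute weights over connections incident to neurons
#' directly connected to each variable's input neuron (the input neuron's
#' immediate neighbourhood).
#'
#' @param model `snn_reservoir` (mapped, for the per-variable part).
#' @return list with `W_a` and data.frame `per_variable`
#'   (`variable_id`, `mean_abs_weight`, `n_connections`).
#' @export
summarize_connectivity <- function(model) {
  stopifnot(inherits(model, "snn_reservoir"))
  if (length(model$weight) == 0) stop("no connections in the reservoir")
  W_a <- mean(abs(model$weight))
  per_variable <- NULL
  if (!is.null(model$input_mapping)) {
    V <- length(model$input_mapping)
    per_variable <- data.frame(variable_id = seq_len(V),
                               mean_abs_weight = NA_real_,
                               n_connections = NA_integer_)
    for (v in seq_len(V)) {
      inp <- model$input_mapping[v]
      # neurons directly connected to the input neuron (either direction)
      nbh <- unique(c(inp,
                      model$post[model$pre == inp],
                      model$pre[model$post == inp]))
      inc <- model$pre %in% nbh | model$post %in% nbh
      per_variable$mean_abs_weight[v] <-
        if (any(inc)) mean(abs(model$weight[inc])) else 0
      per_variable$n_connections[v] <- sum(inc)
    }
  }
  list(W_a = W_a, per_variable = per_variable)
}

#' Export connection triplets and per-variable weights
#'
#' @param model `snn_reservoir`.
#' @param connections_path CSV path for `pre,post,weight` triplets.
#' @param per_variable_path optional CSV path for per-variable mean
#'   absolute weights.
#' @export
write_connectivity <- function(model, connections_path,
                               per_variable_path = NULL) {
  df <- data.frame(pre = model$pre, post = model$post,
                   weight = sprintf("%.17g", model$weight))
  write.csv(df, connections_path, row.names = FALSE, quote = FALSE)
  if (!is.null(per_variable_path)) {
    s <- summarize_connectivity(model)
    pv <- s$per_variable
    pv$mean_abs_weight <- sprintf("%.17g", pv$mean_abs_weight)
    write.csv(pv, per_variable_path, row.names = FALSE, quote = FALSE)
  }
  invisible(connections_path)
}
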