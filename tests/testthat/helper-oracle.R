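# Independent scalar reference implementations, written straight from the
# documented update rules with plain R loops.  They never call the package's
# compiled code and exist solely to cross-check it.

# Reference LIF + STDP simulator for one subject.
#   conn: data.frame(pre, post, weight); inputs: neuron id per variable;
#   spikes: T x V matrix in {-1,0,+1}.
# Per step: u <- leak*u; deliver weights of connections whose pre fired at
# t-1 (each delivery is one transmission); add input currents; refractory
# neurons are clamped to 0 and cannot fire; u >= threshold fires, resets,
# becomes refractory.  STDP: potentiate |w| by rate when pre fired at t-1
# and post fires at t (applied first), depress |w| by rate (floor 0) when
# post fired at t-1 and pre fires at t.  Signs never change.
oracle_lif <- function(n_neurons, conn, inputs, spikes, leak, threshold,
                       refractory, stdp_rate) {
  Tn <- nrow(spikes)
  nv <- ncol(spikes)
  nk <- nrow(conn)
  mag <- abs(conn$weight)
  sgn <- ifelse(conn$weight < 0, -1, 1)
  u <- rep(0, n_neurons)
  refr <- rep(0L, n_neurons)
  prev <- rep(FALSE, n_neurons)
  raster <- matrix(0L, Tn, n_neurons)
  trans <- rep(0, nk)
  events <- list()
  for (t in seq_len(Tn)) {
    u <- u * leak
    for (k in seq_len(nk)) {
      if (prev[conn$pre[k]]) {
        u[conn$post[k]] <- u[conn$post[k]] + sgn[k] * mag[k]
        trans[k] <- trans[k] + 1
        events[[length(events) + 1]] <- c(t, conn$pre[k], conn$post[k])
      }
    }
    for (v in seq_len(nv)) {
      if (spikes[t, v] != 0)
        u[inputs[v]] <- u[inputs[v]] + spikes[t, v]
    }
    cur <- rep(FALSE, n_neurons)
    for (i in seq_len(n_neurons)) {
      if (refr[i] > 0) {
        refr[i] <- refr[i] - 1L
        u[i] <- 0
      } else if (u[i] >= threshold) {
        cur[i] <- TRUE
        u[i] <- 0
        refr[i] <- as.integer(refractory)
      }
    }
    if (stdp_rate > 0) {
      for (k in seq_len(nk))
        if (prev[conn$pre[k]] && cur[conn$post[k]])
          mag[k] <- mag[k] + stdp_rate
      for (k in seq_len(nk))
        if (cur[conn$pre[k]] && prev[conn$post[k]])
          mag[k] <- max(0, mag[k] - stdp_rate)
    }
    raster[t, ] <- as.integer(cur)
    prev <- cur
  }
  ev <- if (length(events)) do.call(rbind, events) else
    matrix(integer(0), 0, 3)
  list(raster = raster, weights = sgn * mag, trans = trans, events = ev)
}

# Reference deSNN weight vector from a raster: rank-order mod^rank over
# first-spike times (ties by neuron id), then per-step drift after the
# first spike, floored at zero.
oracle_desnn <- function(raster, mod, drift) {
  Tn <- nrow(raster); N <- ncol(raster)
  first <- rep(NA_integer_, N)
  for (i in seq_len(N)) {
    f <- which(raster[, i] != 0)
    if (length(f)) first[i] <- f[1]
  }
  ord <- order(first, seq_len(N), na.last = NA)
  w <- rep(0, N)
  for (r in seq_along(ord)) w[ord[r]] <- mod^(r - 1)
  for (i in seq_len(N)) {
    if (is.na(first[i])) next
    if (first[i] < Tn) {
      for (t in (first[i] + 1):Tn) {
        w[i] <- w[i] + if (raster[t, i] != 0) drift else -drift
        if (w[i] < 0) w[i] <- 0
      }
    }
  }
  w
}

# Exhaustive graph-matching optimum for small instances.
oracle_gm_optimum <- function(S, K) {
  V <- nrow(S)
  perms <- gtools_permutations(V)
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    o <- sum(S * K[p, p])
    if (o > best) best <- o
  }
  best
}

# all permutations of 1..n (n small), no external dependency
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# small deterministic toy reservoir used across tests
toy_model <- function(n_neurons, conn, inputs, params) {
  grid <- neuron_grid(c(n_neurons, 1, 1))
  model <- structure(
    list(grid = grid, pre = as.integer(conn$pre),
         post = as.integer(conn$post), weight = as.numeric(conn$weight),
         input_mapping = NULL, params = params, init_seed = 0L),
    class = "snn_reservoir")
  set_input_mapping(model, inputs)
}

toy_spike_trains <- function(spikes_list, months = NULL) {
  # spikes_list: per subject, a T x V matrix
  S <- length(spikes_list)
  Tn <- nrow(spikes_list[[1]]); V <- ncol(spikes_list[[1]])
  arr <- array(0L, dim = c(S, V, Tn))
  for (s in seq_len(S)) arr[s, , ] <- t(spikes_list[[s]])
  structure(
    list(spikes = arr, months = if (is.null(months)) seq_len(Tn) else months,
         subject_id = paste0("toy_", seq_len(S)),
         group = factor(rep("HC", S), levels = c("HC", "Remitter", "Maintained")),
         sigma = rep(1, V), params = encoding_params()),
    class = "spike_trains")
}
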