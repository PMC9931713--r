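#' Map input variables to reservoir sites by graph matching
#'
#' Places the input variables on a set of candidate neuron sites so that
#' variables with correlated spike activity sit close together in the 3D
#' grid.  The similarity `S(u, v)` is the Pearson correlation of the two
#' variables' exponentially smoothed spike trains pooled over the training
#' subjects; the assignment maximises
#' `sum_{u != v} S(u, v) * K(site_u, site_v)` with `K` the inverse
#' Euclidean distance.  Optimisation is greedy seeding followed by
#' pairwise-swap hill climbing, with seeded random restarts; the best local
#' optimum is returned, deterministically for a given seed.
#'
#' @param sts `spike_trains` of the training subjects.
#' @param grid a [neuron_grid()].
#' @param sites integer vector of candidate neuron ids (one per variable);
#'   default [input_sites()] of the grid.
#' @param seed seed for the random restarts.
#' @param smoothing_decay exponential smoothing factor in `[0, 1)` applied
#'   to the spike trains before correlating (default 0.5).
#' @param n_restarts number of random-permutation restarts in addition to
#'   the greedy start (default 5).
#' @return named integer vector variable id -> neuron id, with attributes
#'   `objective` (final objective value) and `similarity` (the S matrix).
#' @export
match_inputs <- function(sts, grid, sites = NULL, seed = 1,
                         smoothing_decay = 0.5, n_restarts = 5) {
  stopifnot(inherits(sts, "spike_trains"), inherits(grid, "neuron_grid"))
  V <- dim(sts$spikes)[2]
  if (is.null(sites)) sites <- input_sites(grid, V)
  if (length(sites) < V) stop("need at least as many candidate sites as variables")
  sites <- sites[seq_len(V)]
  S <- spike_similarity(sts, smoothing_decay)
  K <- site_kernel(grid, sites)
  assign_sites(S, K, sites, seed, n_restarts)
}

# Pearson correlation of exponentially smoothed spike trains pooled over
# subjects (smoothing restarts at each subject boundary).
spike_similarity <- function(sts, decay = 0.5) {
  dm <- dim(sts$spikes)
  V <- dm[2]; Tn <- dm[3]; S <- dm[1]
  pooled <- matrix(0, nrow = S * Tn, ncol = V)
  for (s in seq_len(S)) {
    x <- t(sts$spikes[s, , ])  # Tn x V
    y <- stats::filter(x, decay, method = "recursive")  # y_t = x_t + decay*y_{t-1}
    pooled[((s - 1) * Tn + 1):(s * Tn), ] <- as.matrix(y)
  }
  sds <- apply(pooled, 2, sd)
  Smat <- matrix(0, V, V)
  ok <- sds > 0
  if (sum(ok) >= 2) Smat[ok, ok] <- cor(pooled[, ok, drop = FALSE])
  diag(Smat) <- 0
  Smat
}

site_kernel <- function(grid, sites) {
  co <- grid$coords[sites, , drop = FALSE]
  D <- as.matrix(dist(co))
  K <- 1 / D
  diag(K) <- 0
  K
}

# objective for assignment perm: variable v sits at site index perm[v]
gm_objective <- function(S, K, perm) {
  sum(S * K[perm, perm])
}

assign_sites <- function(S, K, sites, seed, n_restarts) {
  V <- nrow(S)
  climb <- function(perm) {
    obj <- gm_objective(S, K, perm)
    repeat {
      improved <- FALSE
      for (i in seq_len(V - 1)) {
        for (j in (i + 1):V) {
          cand <- perm
          cand[c(i, j)] <- perm[c(j, i)]
          o <- gm_objective(S, K, cand)
          if (o > obj + 1e-12) {
            perm <- cand; obj <- o; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    list(perm = perm, obj = obj)
  }

  # greedy seed: place variables in order of total absolute similarity,
  # each at the free site maximising the partial objective
  ord <- order(rowSums(abs(S)), decreasing = TRUE)
  perm <- integer(V)
  free <- rep(TRUE, V)
  for (v in ord) {
    placed <- which(perm > 0)
    best_site <- NA_integer_; best_gain <- -Inf
    for (s in which(free)) {
      gain <- if (length(placed) == 0) 0 else
        sum(S[v, placed] * K[s, perm[placed]]) +
        sum(S[placed, v] * K[perm[placed], s])
      if (gain > best_gain) { best_gain <- gain; best_site <- s }
    }
    perm[v] <- best_site
    free[best_site] <- FALSE
  }
  best <- climb(perm)

  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) sample.int(V))
  })
  for (st in starts) {
    res <- climb(st)
    if (res$obj > best$obj + 1e-12) best <- res
  }

  mapping <- sites[best$perm]
  names(mapping) <- seq_len(V)
  attr(mapping, "objective") <- best$obj
  attr(mapping, "similarity") <- S
  mapping
}
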