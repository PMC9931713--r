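#' Spike-encoding parameters
#'
#' The encoder marks significant upward (+1) and downward (-1) changes of
#' each variable's time series.  With the default `sd_of_diff` scaling the
#' printed threshold of 0.50 means "half a standard deviation of that
#' variable's step-to-step changes over the training cohort"; `absolute`
#' mode compares raw differences against the threshold directly.
#'
#' @param threshold positive encoding threshold (default 0.50).
#' @param scale_mode `"sd_of_diff"` (default) or `"absolute"`.
#' @return object of class `encoding_params`.
#' @export
encoding_params <- function(threshold = 0.50,
                            scale_mode = c("sd_of_diff", "absolute")) {
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(threshold = threshold, scale_mode = match.arg(scale_mode)),
            class = "encoding_params")
}

#' Threshold-based spike encoding of normalized time series
#'
#' For each variable v and step t > 0 with difference
#' `d = x(t) - x(t-1)`: emit +1 if `d > theta * s_v`, -1 if
#' `d < -theta * s_v`, else 0, where `s_v` is the SD of variable v's
#' consecutive differences pooled over the supplied (training) cohort in
#' `sd_of_diff` mode, or 1 in `absolute` mode.  The first time step never
#' spikes (no predecessor).  A constant variable (`s_v = 0`) emits no
#' spikes.
#'
#' @param tsm a normalized `ts_matrix`.
#' @param params [encoding_params()].
#' @param sigma optional per-variable difference SDs fitted on the training
#'   cohort; pass the `$sigma` of a training-set `spike_trains` when
#'   encoding test subjects so no test information is used.
#' @return object of class `spike_trains`: integer array subjects x
#'   variables x time steps with values in `{-1, 0, +1}`, carrying `$sigma`.
#' @export
encode_threshold <- function(tsm, params = encoding_params(), sigma = NULL) {
  stopifnot(inherits(tsm, "ts_matrix"), inherits(params, "encoding_params"))
  if (!tsm$normalized) stop("series must be normalized before encoding")
  dm <- dim(tsm$values)
  V <- dm[2]; Tn <- dm[3]
  if (Tn < 2) stop("need at least two time steps to encode changes")

  diffs <- tsm$values[, , -1, drop = FALSE] -
    tsm$values[, , -Tn, drop = FALSE]

  if (params$scale_mode == "absolute") {
    sigma <- rep(1, V)
  } else if (is.null(sigma)) {
    sigma <- vapply(seq_len(V), function(v) {
      d <- as.vector(diffs[, v, ])
      sqrt(mean((d - mean(d))^2))  # population SD over all pooled differences
    }, numeric(1))
  } else if (length(sigma) != V) {
    stop("sigma must have one entry per variable")
  }

  spikes <- array(0L, dim = dm)
  for (v in seq_len(V)) {
    if (sigma[v] == 0) next  # constant variable: no spikes
    cut <- params$threshold * sigma[v]
    d <- diffs[, v, , drop = FALSE]
    sp <- array(0L, dim = dim(d))
    sp[d > cut] <- 1L
    sp[d < -cut] <- -1L
    spikes[, v, -1] <- sp
  }
  structure(
    list(spikes = spikes, months = tsm$months, subject_id = tsm$subject_id,
         group = tsm$group, sigma = sigma, params = params),
    class = "spike_trains"
  )
}

#' @export
print.spike_trains <- function(x, ...) {
  dm <- dim(x$spikes)
  cat("spike_trains:", dm[1], "subjects x", dm[2], "variables x", dm[3],
      "steps;", sum(x$spikes != 0), "spikes\n")
  invisible(x)
}

#' Per-variable spike rates
#'
#' Quality-control summary: the fraction of time steps carrying a positive
#' and a negative spike, per variable, pooled over subjects.
#'
#' @param sts a `spike_trains` object.
#' @return data.frame `variable_id`, `positive_rate`, `negative_rate`.
#' @export
spike_rate_summary <- function(sts) {
  stopifnot(inherits(sts, "spike_trains"))
  V <- dim(sts$spikes)[2]
  pos <- vapply(seq_len(V), function(v) mean(sts$spikes[, v, ] == 1L),
                numeric(1))
  neg <- vapply(seq_len(V), function(v) mean(sts$spikes[, v, ] == -1L),
                numeric(1))
  data.frame(variable_id = seq_len(V), positive_rate = pos,
             negative_rate = neg)
}

#' Export nonzero spikes as CSV
#'
#' @param sts a `spike_trains` object.
#' @param path file path.
#' @export
write_spikes <- function(sts, path) {
  stopifnot(inherits(sts, "spike_trains"))
  idx <- which(sts$spikes != 0L, arr.ind = TRUE)
  long <- data.frame(
    subject_id = sts$subject_id[idx[, 1]],
    variable_id = idx[, 2],
    step = idx[, 3],
    spike = sts$spikes[idx]
  )
  long <- long[order(match(long$subject_id, sts$subject_id),
                     long$variable_id, long$step), , drop = FALSE]
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
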