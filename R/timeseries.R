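#' Interpolation grid over the visit schedule
#'
#' The grid keeps every visit month and adds artificial points equally
#' spaced within each inter-visit interval.  When the artificial points do
#' not divide evenly over the intervals, the earliest intervals receive one
#' extra point each, so `total_points` is honoured exactly.
#'
#' @param visit_months strictly increasing visit months.
#' @param total_points total grid size (visits + artificial points).
#' @return numeric vector of months of length `total_points`, containing
#'   `visit_months` exactly.
#' @export
interpolation_grid <- function(visit_months, total_points) {
  K <- length(visit_months)
  if (any(diff(visit_months) <= 0)) stop("visit months must be strictly increasing")
  if (total_points < K)
    stop("total_points must be at least the number of visits (", K, ")")
  n_art <- total_points - K
  n_int <- K - 1
  per <- rep(n_art %/% n_int, n_int)
  extra <- n_art %% n_int
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  grid <- numeric(0)
  for (i in seq_len(n_int)) {
    seg <- seq(visit_months[i], visit_months[i + 1], length.out = per[i] + 2)
    seg[1] <- visit_months[i]            # endpoints bit-exact
    seg[length(seg)] <- visit_months[i + 1]
    grid <- c(grid, seg[-length(seg)])
  }
  c(grid, visit_months[K])
}

#' Linearly interpolate visit measurements to a dense time series
#'
#' Turns the five-visit measurements into a dense series on the grid of
#' [interpolation_grid()].  Values at visit months are preserved bit-exactly
#' and every artificial point is the exact linear interpolant between its
#' bracketing visits, so interpolation never alters the trend of the
#' original data.
#'
#' @param dataset a `cohort_dataset`.
#' @param total_points total number of time points (default 250: the five
#'   visits plus 245 artificial monthly-scale points over 24 months).
#' @return object of class `ts_matrix` (subjects x variables x time steps).
#' @export
interpolate_linear <- function(dataset, total_points = 250) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  months <- interpolation_grid(dataset$visit_months, total_points)
  vm <- dataset$visit_months
  K <- length(vm)
  Tn <- length(months)

  # bracketing interval and weight for every grid point
  iv <- findInterval(months, vm, rightmost.closed = TRUE)
  iv[iv >= K] <- K - 1L
  w <- (months - vm[iv]) / (vm[iv + 1] - vm[iv])

  vals <- unname(dataset$values)
  out <- array(NA_real_, dim = c(dim(vals)[1], dim(vals)[2], Tn))
  at_knot <- months %in% vm
  for (t in seq_len(Tn)) {
    if (at_knot[t]) {
      out[, , t] <- vals[, , match(months[t], vm)]
    } else {
      # y1 + w*(y2 - y1): exact at w = 0 and for constant segments
      y1 <- vals[, , iv[t]]
      out[, , t] <- y1 + w[t] * (vals[, , iv[t] + 1] - y1)
    }
  }
  new_ts_matrix(out, months, dataset)
}

new_ts_matrix <- function(values, months, parent,
                          normalized = FALSE, norm_params = NULL) {
  structure(
    list(values = values, months = months,
         subject_id = parent$subject_id, group = parent$group,
         normalized = normalized, norm_params = norm_params),
    class = "ts_matrix"
  )
}

#' @export
print.ts_matrix <- function(x, ...) {
  dm <- dim(x$values)
  cat("ts_matrix:", dm[1], "subjects x", dm[2], "variables x", dm[3],
      "time steps;", if (x$normalized) "normalized" else "raw", "\n")
  invisible(x)
}

#' Normalize a time-series matrix per variable
#'
#' Min-max normalization (default) maps each variable to `[0, 1]` using its
#' range over the whole supplied cohort; z-scoring standardises to mean 0,
#' SD 1.  Fitting on a training partition and passing the returned
#' parameters when normalizing test subjects prevents information leakage in
#' cross-validation.
#'
#' @param tsm a raw `ts_matrix`.
#' @param mode `"minmax"` or `"zscore"`.
#' @param params optional normalization parameters fitted on another (i.e.
#'   training) partition, as found in `$norm_params` of a normalized series.
#' @return normalized `ts_matrix` carrying `norm_params`.  A constant
#'   variable is mapped to 0.5 (min-max) or 0 (z-score) with a warning.
#' @export
normalize_series <- function(tsm, mode = c("minmax", "zscore"), params = NULL) {
  stopifnot(inherits(tsm, "ts_matrix"))
  if (tsm$normalized) stop("series is already normalized")
  mode <- match.arg(mode)
  V <- dim(tsm$values)[2]

  if (is.null(params)) {
    params <- data.frame(variable = seq_len(V), a = NA_real_, b = NA_real_)
    for (v in seq_len(V)) {
      x <- tsm$values[, v, ]
      if (mode == "minmax") {
        params$a[v] <- min(x); params$b[v] <- max(x)
      } else {
        params$a[v] <- mean(x); params$b[v] <- sd(x)
      }
    }
    attr(params, "mode") <- mode
  } else {
    mode <- attr(params, "mode")
    if (is.null(mode)) stop("params must carry a 'mode' attribute")
  }

  out <- tsm$values
  for (v in seq_len(V)) {
    a <- params$a[v]; b <- params$b[v]
    if (mode == "minmax") {
      if (b == a) {
        warning("variable ", v, " is constant; mapped to 0.5")
        out[, v, ] <- 0.5
      } else {
        out[, v, ] <- (tsm$values[, v, ] - a) / (b - a)
      }
    } else {
      if (b == 0) {
        warning("variable ", v, " is constant; mapped to 0")
        out[, v, ] <- 0
      } else {
        out[, v, ] <- (tsm$values[, v, ] - a) / b
      }
    }
  }
  new_ts_matrix(out, tsm$months, tsm, normalized = TRUE, norm_params = params)
}

#' Truncate a time series at a month
#'
#' Keeps only time steps at or before `up_to_month`.  Used to build the
#' prediction-task test inputs (e.g. only the first 18 months of a 24-month
#' series).
#'
#' @param tsm a `ts_matrix`.
#' @param up_to_month last month to retain.
#' @return truncated `ts_matrix`.
#' @export
truncate_series <- function(tsm, up_to_month) {
  stopifnot(inherits(tsm, "ts_matrix"))
  if (up_to_month < tsm$months[1])
    stop("up_to_month is before the first time point")
  keep <- tsm$months <= up_to_month
  new_ts_matrix(tsm$values[, , keep, drop = FALSE], tsm$months[keep], tsm,
                normalized = tsm$normalized, norm_params = tsm$norm_params)
}

#' Subset a time-series matrix by subjects
#'
#' @param tsm a `ts_matrix`.
#' @param idx integer or logical subject index.
#' @return `ts_matrix` with the selected subjects.
#' @export
subset_series <- function(tsm, idx) {
  stopifnot(inherits(tsm, "ts_matrix"))
  parent <- list(subject_id = tsm$subject_id[idx], group = tsm$group[idx])
  new_ts_matrix(tsm$values[idx, , , drop = FALSE], tsm$months, parent,
                normalized = tsm$normalized, norm_params = tsm$norm_params)
}

#' Export an interpolated series as long CSV
#'
#' @param tsm a `ts_matrix`.
#' @param path file path.
#' @export
write_series <- function(tsm, path) {
  stopifnot(inherits(tsm, "ts_matrix"))
  dm <- dim(tsm$values)
  long <- data.frame(
    subject_id = rep(tsm$subject_id, times = dm[2] * dm[3]),
    variable_id = rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
    month = rep(tsm$months, each = dm[1] * dm[2]),
    value_interp = sprintf("%.17g", as.vector(tsm$values))
  )
  long <- long[order(match(long$subject_id, tsm$subject_id),
                     long$variable_id, long$month), , drop = FALSE]
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
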