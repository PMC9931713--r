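GROUP_LEVELS <- c("HC", "Remitter", "Maintained")

#' Construct a group trajectory profile
#'
#' A profile describes how one outcome group's 23 variables evolve over the
#' visit schedule, all on a z-score scale: a per-variable baseline mean, a
#' per-variable deterministic change per visit, a loading of each variable on
#' one shared latent random-walk factor, a coupling strength scaling that
#' factor (this is what makes variables co-move), and a residual noise SD.
#'
#' @param group_label one of `"HC"`, `"Remitter"`, `"Maintained"`.
#' @param baseline_mean per-variable baseline mean (z-units); scalars are
#'   recycled to 23 variables.
#' @param visit_deltas per-variable deterministic change per visit (z/visit).
#' @param latent_loadings per-variable loading on the shared latent factor.
#' @param coupling_strength scalar `>= 0` scaling the latent factor; larger
#'   values produce stronger cross-variable co-movement.
#' @param noise_sd per-variable residual SD (z-units), `> 0`.
#' @param n_variables number of variables (23 for the shipped catalogue).
#' @return object of class `group_profile`.
#' @export
group_profile <- function(group_label, baseline_mean, visit_deltas,
                          latent_loadings, coupling_strength, noise_sd,
                          n_variables = 23) {
  group_label <- match.arg(group_label, GROUP_LEVELS)
  rec <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 1) x <- rep(x, n_variables)
    if (length(x) != n_variables)
      stop("profile fields must have length 1 or ", n_variables)
    x
  }
  noise_sd <- rec(noise_sd)
  if (any(noise_sd <= 0)) stop("noise_sd must be > 0")
  if (coupling_strength < 0) stop("coupling_strength must be >= 0")
  structure(
    list(
      group_label = group_label,
      baseline_mean = rec(baseline_mean),
      visit_deltas = rec(visit_deltas),
      latent_loadings = rec(latent_loadings),
      coupling_strength = as.numeric(coupling_strength),
      noise_sd = noise_sd
    ),
    class = "group_profile"
  )
}

#' Default group profiles for the synthetic cohort
#'
#' The shipped defaults encode the qualitative group structure the analysis
#' assumes: healthy controls (HC) score high and stay stable; Remitters
#' start impaired — deeply so on the verbal and working memory variables
#' (ids 1--2), mildly on the rest — and every variable recovers to the HC
#' level by month 24; the Maintained group stays persistently impaired
#' with no systematic trend but strong, broad cross-variable coupling and
#' the largest visit-to-visit variability.  The coupling strength is
#' ordered Maintained > Remitter > HC, so the Maintained group shows the
#' strongest co-movement (hence interaction) between variables.
#'
#' @return named list of three `group_profile` objects (`HC`, `Remitter`,
#'   `Maintained`).
#' @export
default_profiles <- function() {
  hc_base <- rep(0.8, 23)
  rem_base <- c(rep(-1.6, 2), rep(0.6, 21))
  list(
    HC = group_profile("HC",
      baseline_mean = hc_base, visit_deltas = 0,
      latent_loadings = 0.8, coupling_strength = 0.05, noise_sd = 0.12),
    Remitter = group_profile("Remitter",
      baseline_mean = rem_base, visit_deltas = (hc_base - rem_base) / 4,
      latent_loadings = 0.8, coupling_strength = 0.1, noise_sd = 0.12),
    Maintained = group_profile("Maintained",
      baseline_mean = -0.8, visit_deltas = 0,
      latent_loadings = 1, coupling_strength = 1.8, noise_sd = 0.30)
  )
}

#' Configuration of a synthetic cohort
#'
#' @param n_per_group named counts per group (default the study sizes
#'   HC = 81, Remitter = 58, Maintained = 30).
#' @param visit_months strictly increasing assessment months starting at 0
#'   (default the five visits 0, 6, 12, 18, 24).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   cohorts.
#' @param profiles named list of three [group_profile()] objects.
#' @param catalog variable catalogue, see [variable_catalog()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(HC = 81, Remitter = 58, Maintained = 30),
                          visit_months = c(0, 6, 12, 18, 24),
                          seed = 1,
                          profiles = default_profiles(),
                          catalog = variable_catalog()) {
  if (!all(GROUP_LEVELS %in% names(n_per_group)))
    stop("n_per_group must name HC, Remitter and Maintained")
  n_per_group <- n_per_group[GROUP_LEVELS]
  if (any(n_per_group <= 0)) stop("group counts must be > 0")
  if (any(diff(visit_months) <= 0)) stop("visit_months must be strictly increasing")
  if (visit_months[1] != 0) stop("first visit month must be 0")
  if (!all(GROUP_LEVELS %in% names(profiles)))
    stop("profiles must name HC, Remitter and Maintained")
  for (g in GROUP_LEVELS)
    if (!inherits(profiles[[g]], "group_profile"))
      stop("profiles must be group_profile objects")
  validate_catalog(catalog)
  structure(
    list(n_per_group = n_per_group, visit_months = as.numeric(visit_months),
         seed = as.integer(seed), profiles = profiles[GROUP_LEVELS],
         catalog = catalog),
    class = "cohort_config"
  )
}

#' Closed-form group mean trajectory
#'
#' Expected value of each variable at each visit under a profile (latent
#' factor and noise have mean zero): `baseline + (k - 1) * visit_delta` at
#' the k-th visit.
#'
#' @param profile a [group_profile()].
#' @param n_visits number of visits.
#' @return matrix variables x visits of expected z-scores.
#' @export
profile_mean_curve <- function(profile, n_visits) {
  sapply(seq_len(n_visits) - 1, function(k)
    profile$baseline_mean + k * profile$visit_deltas)
}

#' Generate a synthetic longitudinal cohort
#'
#' Each subject draws one shared latent factor path (a standard-normal
#' random walk over visits, starting at 0) and each variable's value at
#' visit k is
#' `baseline[v] + (k-1) * delta[v] + coupling * loading[v] * L_k + noise`.
#' The latent factor is what couples variables within a subject; its weight
#' (`coupling_strength`) differs by group.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort_dataset`: a complete subjects x
#'   variables x visits array plus group labels.  No values are missing —
#'   the design mirrors a complete-case inclusion rule.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  months <- config$visit_months
  K <- length(months)
  V <- nrow(config$catalog)
  n_total <- sum(config$n_per_group)

  with_seed(config$seed, {
    values <- array(NA_real_, dim = c(n_total, V, K))
    subject_id <- character(n_total)
    group <- character(n_total)
    row <- 0L
    for (g in GROUP_LEVELS) {
      prof <- config$profiles[[g]]
      mean_curve <- profile_mean_curve(prof, K)  # V x K
      for (s in seq_len(config$n_per_group[[g]])) {
        row <- row + 1L
        subject_id[row] <- sprintf("%s_%03d", g, s)
        group[row] <- g
        latent <- cumsum(c(0, rnorm(K - 1)))
        noise <- matrix(rnorm(V * K, sd = prof$noise_sd), nrow = V)
        values[row, , ] <- mean_curve +
          prof$coupling_strength * outer(prof$latent_loadings, latent) +
          noise
      }
    }
    dimnames(values) <- list(subject_id, config$catalog$variable_id, months)
    structure(
      list(values = values,
           subject_id = subject_id,
           group = factor(group, levels = GROUP_LEVELS),
           visit_months = months,
           catalog = config$catalog),
      class = "cohort_dataset"
    )
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:", length(x$subject_id), "subjects x",
      dim(x$values)[2], "variables x", length(x$visit_months), "visits\n")
  print(table(x$group))
  invisible(x)
}

#' Subset a cohort by subjects
#'
#' @param dataset a `cohort_dataset`.
#' @param idx integer or logical subject index.
#' @return a `cohort_dataset` containing only the selected subjects.
#' @export
subset_cohort <- function(dataset, idx) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  structure(
    list(values = dataset$values[idx, , , drop = FALSE],
         subject_id = dataset$subject_id[idx],
         group = dataset$group[idx],
         visit_months = dataset$visit_months,
         catalog = dataset$catalog),
    class = "cohort_dataset"
  )
}
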