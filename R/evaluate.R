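#' Balanced accuracy of a confusion matrix
#'
#' For two classes this is `(sensitivity + specificity) / 2`; for more
#' classes it is the macro average of per-class recall, which reduces to
#' the two-class formula.  Rows are true classes, columns predictions.  A
#' class absent from the test fold is excluded from the macro average with
#' a warning.
#'
#' @param confusion square numeric matrix with matching row/column names.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || nrow(confusion) == 0)
    stop("confusion must be a nonempty square matrix")
  n_true <- rowSums(confusion)
  present <- n_true > 0
  if (!any(present)) stop("confusion matrix has no observations")
  if (any(!present))
    warning("class(es) absent from the test fold excluded from the macro ",
            "average: ", paste(rownames(confusion)[!present], collapse = ", "))
  recalls <- diag(confusion)[present] / n_true[present]
  mean(recalls)
}

#' Experiment configuration
#'
#' Bundles every tunable of the classification / prediction experiment.
#' Defaults are the analysis defaults: 250 time points, a 10 x 10 x 10
#' reservoir with radius-2 small-world connectivity, encoding and firing
#' thresholds of 0.50, STDP rate 0.01, deSNN mod 0.8 and drift 0.005, and
#' 30 repeats of stratified 50/50 two-fold cross-validation (test series
#' truncated at month 18 for the prediction task).
#'
#' @param task `"classification"` (full-length test series) or
#'   `"prediction"` (test series truncated at `truncation_month`).
#' @param n_repeats number of repeated splits (default 30).
#' @param split_fraction training fraction (default 0.5).
#' @param stratified stratify the split by class (default `TRUE`).
#' @param truncation_month last month of test inputs in the prediction
#'   task (default 18).
#' @param master_seed single integer seeding the whole experiment.
#' @param total_points interpolation grid size (default 250).
#' @param grid_dims reservoir dimensions (default `c(10, 10, 10)`).
#' @param encoding [encoding_params()].
#' @param reservoir [reservoir_params()].
#' @param desnn [desnn_params()].
#' @param passes STDP presentation passes over the training subjects.
#' @param norm_mode normalization mode (default `"minmax"`).
#' @param gm_restarts graph-matching random restarts (default 5).
#' @param two_fold if `TRUE` (default) both halves serve once as test per
#'   repeat; if `FALSE` only the second half is tested.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(task = c("classification", "prediction"),
                              n_repeats = 30, split_fraction = 0.5,
                              stratified = TRUE, truncation_month = 18,
                              master_seed = 1, total_points = 250,
                              grid_dims = c(10, 10, 10),
                              encoding = encoding_params(),
                              reservoir = reservoir_params(),
                              desnn = desnn_params(),
                              passes = 1, norm_mode = "minmax",
                              gm_restarts = 5, two_fold = TRUE) {
  task <- match.arg(task)
  stopifnot(split_fraction > 0, split_fraction < 1, n_repeats >= 1)
  structure(
    list(task = task, n_repeats = as.integer(n_repeats),
         split_fraction = split_fraction, stratified = stratified,
         truncation_month = truncation_month,
         master_seed = as.integer(master_seed),
         total_points = total_points, grid_dims = grid_dims,
         encoding = encoding, reservoir = reservoir, desnn = desnn,
         passes = passes, norm_mode = norm_mode,
         gm_restarts = gm_restarts, two_fold = two_fold),
    class = "experiment_config"
  )
}

subset_spikes <- function(sts, idx) {
  structure(
    list(spikes = sts$spikes[idx, , , drop = FALSE], months = sts$months,
         subject_id = sts$subject_id[idx], group = sts$group[idx],
         sigma = sts$sigma, params = sts$params),
    class = "spike_trains"
  )
}

stratified_split <- function(group, fraction, stratified, seed) {
  with_seed(seed, {
    if (stratified) {
      a <- integer(0)
      for (g in levels(group)) {
        members <- which(group == g)
        if (length(members) < 2)
          stop("class ", g, " has fewer than 2 subjects")
        take <- ceiling(length(members) * fraction)
        a <- c(a, sample(members)[seq_len(take)])
      }
    } else {
      a <- sample(seq_along(group))[seq_len(ceiling(length(group) * fraction))]
    }
    sort(a)
  })
}

# one train/test fold of the full pipeline; returns the confusion matrix
run_fold <- function(tsm_raw, train_idx, test_idx, config, seeds) {
  tr_raw <- subset_series(tsm_raw, train_idx)
  te_raw <- subset_series(tsm_raw, test_idx)

  # all data-dependent fitting on the training half only
  tr <- normalize_series(tr_raw, config$norm_mode)
  te <- normalize_series(te_raw, params = tr$norm_params)
  enc_tr <- encode_threshold(tr, config$encoding)
  if (config$task == "prediction")
    te <- truncate_series(te, config$truncation_month)
  enc_te <- encode_threshold(te, config$encoding, sigma = enc_tr$sigma)

  grid <- neuron_grid(config$grid_dims)
  V <- dim(enc_tr$spikes)[2]
  mapping <- match_inputs(enc_tr, grid, input_sites(grid, V),
                          seed = seeds[["gm"]],
                          n_restarts = config$gm_restarts)
  model <- init_small_world(grid, config$reservoir, seed = seeds[["init"]])
  model <- set_input_mapping(model, mapping)
  trained <- train_stdp(model, enc_tr, passes = config$passes,
                        order_seed = seeds[["order"]])$model

  clf <- fit_desnn(enc_tr, labels = enc_tr$group, params = config$desnn,
                   model = trained)

  lev <- levels(tsm_raw$group)
  confusion <- matrix(0L, length(lev), length(lev),
                      dimnames = list(true = lev, predicted = lev))
  Wte <- desnn_matrix(trained, enc_te, config$desnn)
  pred <- classify_desnn(clf, Wte)$predicted_label
  for (s in seq_along(test_idx)) {
    confusion[as.character(enc_te$group[s]), pred[s]] <-
      confusion[as.character(enc_te$group[s]), pred[s]] + 1L
  }
  confusion
}

#' Run a repeated two-fold cross-validated experiment
#'
#' For each repeat, the cohort is split into stratified random halves and
#' each half serves once as training and once as test set.  Each fold runs
#' the full pipeline from scratch — training-half normalization and
#' encoding scale, graph-matched input mapping, a freshly initialised
#' small-world reservoir, STDP, and the deSNN readout — so no test
#' information leaks into any fitted quantity.  In the prediction task,
#' training uses the full-length series and only the test inputs are
#' truncated at `truncation_month`.
#'
#' @param dataset a `cohort_dataset` with at least two classes.
#' @param config an [experiment_config()].
#' @return object of class `evaluation_result`: fold-level balanced
#'   accuracies and confusion matrices, per-class mean recall, and the
#'   mean/SD balanced accuracy.
#' @export
run_experiment <- function(dataset, config) {
  stopifnot(inherits(dataset, "cohort_dataset"),
            inherits(config, "experiment_config"))
  if (nlevels(droplevels(dataset$group)) < 2)
    stop("dataset must contain at least two classes")
  if (config$task == "prediction" &&
      config$truncation_month < dataset$visit_months[1])
    stop("invalid truncation_month")

  tsm_raw <- interpolate_linear(dataset, config$total_points)
  n <- length(dataset$subject_id)
  seeds <- matrix(seed_stream(config$master_seed, config$n_repeats * 7),
                  nrow = config$n_repeats)

  folds <- list()
  for (r in seq_len(config$n_repeats)) {
    half_a <- stratified_split(dataset$group, config$split_fraction,
                               config$stratified, seeds[r, 1])
    half_b <- setdiff(seq_len(n), half_a)
    fold_sets <- list(list(train = half_a, test = half_b),
                      list(train = half_b, test = half_a))
    if (!config$two_fold) fold_sets <- fold_sets[1]
    for (f in seq_along(fold_sets)) {
      fs <- fold_sets[[f]]
      sd <- c(gm = seeds[r, 2 * f], init = seeds[r, 2 * f + 1],
              order = seeds[r, f + 5])
      confusion <- run_fold(tsm_raw, fs$train, fs$test, config, sd)
      folds[[length(folds) + 1]] <- list(
        repeat_id = r, fold = f, confusion = confusion,
        balanced_accuracy = balanced_accuracy(confusion))
    }
  }

  ba <- vapply(folds, `[[`, numeric(1), "balanced_accuracy")
  lev <- levels(dataset$group)
  recall_mat <- t(vapply(folds, function(fd) {
    cm <- fd$confusion
    diag(cm) / pmax(rowSums(cm), 1)
  }, numeric(length(lev))))
  per_class <- colMeans(recall_mat)
  names(per_class) <- lev

  structure(
    list(task = config$task, folds = folds,
         balanced_accuracy_mean = mean(ba), balanced_accuracy_sd = sd(ba),
         per_class_recall = per_class,
         fold_table = data.frame(
           repeat_id = vapply(folds, `[[`, numeric(1), "repeat_id"),
           fold = vapply(folds, `[[`, numeric(1), "fold"),
           balanced_accuracy = ba)),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("evaluation_result (", x$task, "): balanced accuracy ",
      sprintf("%.3f", x$balanced_accuracy_mean), " (sd ",
      sprintf("%.3f", x$balanced_accuracy_sd), ") over ",
      length(x$folds), " folds\n", sep = "")
  print(round(x$per_class_recall, 3))
  invisible(x)
}

#' Export fold-level evaluation results
#'
#' Writes one row per fold and class with that fold's recall and balanced
#' accuracy.
#'
#' @param result an `evaluation_result`.
#' @param path CSV path.
#' @export
write_evaluation <- function(result, path) {
  rows <- list()
  for (fd in result$folds) {
    cm <- fd$confusion
    rec <- diag(cm) / pmax(rowSums(cm), 1)
    rows[[length(rows) + 1]] <- data.frame(
      repeat_id = fd$repeat_id, fold = fd$fold,
      class = rownames(cm), recall = sprintf("%.17g", rec),
      balanced_accuracy = sprintf("%.17g", fd$balanced_accuracy))
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Train one reservoir per group and extract interaction summaries
#'
#' The visualisation experiment: the whole cohort is interpolated,
#' normalized and encoded once, then each group's subjects train their own
#' reservoir (identical seeds across groups, so differences reflect the
#' data), and each trained model is summarised by its connection weights
#' and feature interaction network.
#'
#' @param dataset a `cohort_dataset`.
#' @param config an [experiment_config()] (CV fields unused here).
#' @param groups which groups to model (default all present).
#' @return named list per group with `model`, `log`, `connectivity`,
#'   `fin`.
#' @export
run_group_visualization <- function(dataset, config = experiment_config(),
                                    groups = levels(dataset$group)) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  for (g in groups)
    if (!any(dataset$group == g)) stop("group ", g, " has no subjects")

  tsm <- normalize_series(interpolate_linear(dataset, config$total_points),
                          config$norm_mode)
  enc <- encode_threshold(tsm, config$encoding)
  grid <- neuron_grid(config$grid_dims)
  V <- dim(enc$spikes)[2]
  seeds <- seed_stream(config$master_seed, 3)

  out <- list()
  for (g in groups) {
    enc_g <- subset_spikes(enc, dataset$group == g)
    mapping <- match_inputs(enc_g, grid, input_sites(grid, V),
                            seed = seeds[1], n_restarts = config$gm_restarts)
    model <- init_small_world(grid, config$reservoir, seed = seeds[2])
    model <- set_input_mapping(model, mapping)
    trained <- train_stdp(model, enc_g, passes = config$passes,
                          order_seed = seeds[3])
    clusters <- cluster_neurons(trained$model)
    out[[g]] <- list(
      model = trained$model, log = trained$log,
      connectivity = summarize_connectivity(trained$model),
      fin = compute_fin(trained$log, clusters, group_label = g))
  }
  out
}
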