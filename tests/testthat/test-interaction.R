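test_that("neurons cluster to the nearest input variable with documented tie-breaks", {
  # 3x3x3 grid, two inputs at opposite corners
  grid <- neuron_grid(c(3, 3, 3))
  conn <- data.frame(pre = 1L, post = 2L, weight = 0.5)
  model <- structure(
    list(grid = grid, pre = conn$pre, post = conn$post, weight = conn$weight,
         input_mapping = NULL, params = reservoir_params(), init_seed = 0L),
    class = "snn_reservoir")
  model <- set_input_mapping(model, c(1L, 27L))  # (1,1,1) and (3,3,3)
  cl <- cluster_neurons(model)
  # brute-force nearest-site partition with lowest-id tie-break (no direct
  # connections to either input for the tied neurons here except neuron 2)
  co <- grid$coords
  expected <- integer(27)
  for (i in 1:27) {
    d1 <- sum((co[i, ] - co[1, ])^2)
    d2 <- sum((co[i, ] - co[27, ])^2)
    expected[i] <- if (d1 < d2) 1L else if (d2 < d1) 2L else 1L
  }
  # neuron 2 is directly connected to input neuron 1 but is strictly closer
  # to it anyway; assignments must agree everywhere
  expect_equal(cl, expected)
  # each input neuron belongs to its own cluster
  expect_equal(cl[1], 1L)
  expect_equal(cl[27], 2L)
  # partition covers every neuron
  expect_length(cl, 27)
})

test_that("equidistant neurons prefer the more strongly connected input", {
  # 3 neurons on a line; inputs at both ends; the middle neuron is
  # equidistant and strongly connected to input 2
  grid <- neuron_grid(c(3, 1, 1))
  model <- structure(
    list(grid = grid, pre = c(2L), post = c(3L), weight = c(0.9),
         input_mapping = NULL, params = reservoir_params(), init_seed = 0L),
    class = "snn_reservoir")
  model <- set_input_mapping(model, c(1L, 3L))
  cl <- cluster_neurons(model)
  expect_equal(cl[2], 2L)  # tie broken by |w|=0.9 link to input neuron 3
  # with no connections at all, the tie falls to the lower variable id
  model$pre <- integer(0); model$post <- integer(0); model$weight <- numeric(0)
  expect_equal(cluster_neurons(model)[2], 1L)
})

test_that("FIN counts conserve the transmission total and match an event recount", {
  set.seed(37)
  for (rep in 1:10) {
    conn <- data.frame(pre = c(1, 2, 3, 4, 1), post = c(2, 3, 4, 1, 3),
                       weight = round(runif(5, 0.3, 0.9), 2))
    model <- toy_model(4, conn, c(1L, 3L),
                       reservoir_params(leak = 0, refractory_steps = 0,
                                        stdp_rate = 0.01))
    spikes <- matrix(sample(c(0L, 1L), 2 * 20, replace = TRUE), 20, 2)
    sts <- toy_spike_trains(list(spikes))
    trained <- train_stdp(model, sts, order_seed = rep, record_events = TRUE)
    cl <- cluster_neurons(trained$model)
    fin <- compute_fin(trained$log, cl)
    # conservation: directed total equals number of transmission events
    expect_equal(sum(fin$counts), trained$log$total)
    if (!is.null(trained$log$events)) {
      expect_equal(sum(fin$counts), nrow(trained$log$events))
      # independent event-by-event recount
      recount <- matrix(0, max(cl), max(cl))
      for (e in seq_len(nrow(trained$log$events))) {
        a <- cl[trained$log$events$pre[e]]
        b <- cl[trained$log$events$post[e]]
        recount[a, b] <- recount[a, b] + 1
      }
      expect_equal(fin$counts, recount)
    }
  }
})

test_that("an empty spike log gives a zero FIN", {
  conn <- data.frame(pre = 1L, post = 2L, weight = 0.5)
  model <- toy_model(2, conn, c(1L, 2L), reservoir_params())
  silent <- toy_spike_trains(list(matrix(0L, 10, 2)))
  trained <- train_stdp(model, silent, order_seed = 1)
  fin <- compute_fin(trained$log, cluster_neurons(trained$model))
  expect_true(all(fin$counts == 0))
  expect_equal(fin$total, 0)
})

test_that("FIN is additive over split logs and symmetrization doubles the total", {
  conn <- data.frame(pre = c(1, 2), post = c(2, 3), weight = 0.8)
  model <- toy_model(3, conn, c(1L, 3L),
                     reservoir_params(leak = 0, refractory_steps = 0))
  mk <- function(seed) {
    set.seed(seed)
    matrix(sample(c(0L, 1L), 30, replace = TRUE), 15, 2)
  }
  sA <- toy_spike_trains(list(mk(1)))
  sB <- toy_spike_trains(list(mk(2)))
  sAB <- toy_spike_trains(list(mk(1), mk(2)))
  cl <- cluster_neurons(model)
  fA <- compute_fin(train_stdp(model, sA, order_seed = 1)$log, cl)
  fB <- compute_fin(train_stdp(model, sB, order_seed = 1)$log, cl)
  # frozen weights for additivity: use stdp_rate 0 so runs do not interact
  model0 <- model
  model0$params$stdp_rate <- 0
  fA0 <- compute_fin(train_stdp(model0, sA, order_seed = 1)$log, cl)
  fB0 <- compute_fin(train_stdp(model0, sB, order_seed = 1)$log, cl)
  fAB0 <- compute_fin(train_stdp(model0, sAB, order_seed = 1)$log, cl)
  expect_equal(fAB0$counts, fA0$counts + fB0$counts)
  sym <- fin_symmetric(fA)
  expect_true(isSymmetric(sym))
  expect_equal(sum(sym), 2 * fA$total)
})

test_that("group comparison tables have one row per group and 23 per variable", {
  d <- generate_cohort(cohort_config(
    n_per_group = c(HC = 3, Remitter = 3, Maintained = 3), seed = 41))
  cfg <- experiment_config(total_points = 30, grid_dims = c(4, 4, 4),
                           master_seed = 2)
  bundle <- run_group_visualization(d, cfg)
  tabs <- compare_groups(bundle)
  expect_equal(nrow(tabs$summary), 3)
  expect_equal(sort(tabs$summary$group), sort(levels(d$group)))
  expect_equal(nrow(tabs$per_variable), 3 * 23)
  # identical data and seeds give identical tables
  bundle2 <- run_group_visualization(d, cfg)
  tabs2 <- compare_groups(bundle2)
  expect_identical(tabs, tabs2)
  # an empty group errors by name
  d2 <- subset_cohort(d, d$group != "Maintained")
  expect_error(run_group_visualization(d2, cfg), "Maintained")
})
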