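test_that("radius-2 candidate pairs on a 3x3x3 grid match brute force", {
  grid <- neuron_grid(c(3, 3, 3))
  pairs <- longsnn:::radius_pairs(grid, 2)
  # brute force over all ordered pairs
  co <- grid$coords
  brute <- 0
  d2s <- c()
  for (i in 1:27) for (j in 1:27) {
    if (i == j) next
    d2 <- sum((co[i, ] - co[j, ])^2)
    if (d2 <= 4) { brute <- brute + 1; d2s <- c(d2s, d2) }
  }
  expect_equal(nrow(pairs), brute)
  expect_setequal(unique(pairs[, "d2"]), c(1, 2, 3, 4))
  expect_setequal(unique(d2s), c(1, 2, 3, 4))
  # radius below the lattice spacing yields no connections
  expect_equal(nrow(longsnn:::radius_pairs(grid, 0.5)), 0)
})

test_that("small-world initialisation is seeded and respects the radius", {
  grid <- neuron_grid(c(5, 5, 5))
  p <- reservoir_params()
  m1 <- init_small_world(grid, p, seed = 11)
  m2 <- init_small_world(grid, p, seed = 11)
  expect_identical(m1$weight, m2$weight)
  expect_identical(m1$pre, m2$pre)
  m3 <- init_small_world(grid, p, seed = 12)
  expect_false(identical(m1$weight, m3$weight))
  # all connections within the radius, none reflexive
  d <- sqrt(rowSums((grid$coords[m1$pre, ] - grid$coords[m1$post, ])^2))
  expect_true(all(d <= p$connection_radius + 1e-12))
  expect_true(all(m1$pre != m1$post))
  # roughly the configured fraction of inhibitory connections
  expect_gt(mean(m1$weight < 0), 0.1)
  expect_lt(mean(m1$weight < 0), 0.3)
})

test_that("input sites are distinct, deterministic and spread out", {
  grid <- neuron_grid(c(10, 10, 10))
  s1 <- input_sites(grid, 23)
  expect_length(unique(s1), 23)
  expect_identical(s1, input_sites(grid, 23))
  co <- grid$coords[s1, ]
  mind <- min(dist(co))
  expect_gt(mind, 2)  # farther apart than the connection radius
})

test_that("LIF simulation matches the scalar reference on toy networks", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:5, 1)
    nk <- sample(2:6, 1)
    conn <- data.frame(
      pre = sample(n, nk, replace = TRUE),
      post = sample(n, nk, replace = TRUE),
      weight = round(runif(nk, -1, 1), 3))
    conn <- conn[conn$pre != conn$post, , drop = FALSE]
    if (nrow(conn) == 0) next
    inputs <- sample(n, 2)
    spikes <- matrix(sample(c(-1L, 0L, 1L), 2 * 25, replace = TRUE,
                            prob = c(0.2, 0.4, 0.4)), 25, 2)
    leak <- sample(c(0, 0.5, 0.9), 1)
    refr <- sample(0:2, 1)
    params <- reservoir_params(leak = leak, refractory_steps = refr,
                               firing_threshold = 0.5)
    model <- toy_model(n, conn, inputs, params)
    raster <- simulate_lif(model, spikes)
    ref <- oracle_lif(n, conn, inputs, spikes, leak, 0.5, refr, 0)
    expect_identical(unclass(raster)[, ], ref$raster,
                     label = paste("raster rep", rep))
  }
})

test_that("single neuron fires once after one input spike", {
  conn <- data.frame(pre = integer(0), post = integer(0), weight = numeric(0))
  model <- toy_model(1, conn, 1L, reservoir_params(leak = 0))
  spikes <- matrix(0L, 10, 1)
  spikes[4, 1] <- 1L
  raster <- simulate_lif(model, spikes)
  expect_equal(which(raster[, 1] == 1L), 4)
  expect_equal(sum(raster), 1)
  # no input, no output
  expect_true(all(simulate_lif(model, matrix(0L, 10, 1)) == 0L))
})

test_that("STDP matches the scalar reference and the additive closed form", {
  # two neurons, pre always fires one step before post
  conn <- data.frame(pre = 1L, post = 2L, weight = 0.4)
  model <- toy_model(2, conn, c(1L, 2L),
                     reservoir_params(leak = 0, stdp_rate = 0.01,
                                      refractory_steps = 0))
  # drive pre at steps 1, 4, ..., 28 and post one step later each time, so
  # the reverse (post-before-pre) pairing never occurs
  Tn <- 30
  sp <- matrix(0L, Tn, 2)
  sp[seq(1, 28, by = 3), 1] <- 1L
  sp[seq(2, 29, by = 3), 2] <- 1L
  sts <- toy_spike_trains(list(sp))
  trained <- train_stdp(model, sts, order_seed = 1)
  # 10 pre-then-post co-firings, each +0.01
  expect_equal(trained$model$weight, 0.4 + 10 * 0.01)
  # no spikes anywhere leaves weights untouched
  silent <- toy_spike_trains(list(matrix(0L, 10, 2)))
  expect_identical(train_stdp(model, silent, order_seed = 1)$model$weight,
                   model$weight)
})

test_that("STDP on random toy networks equals the oracle exactly", {
  set.seed(31)
  for (rep in 1:8) {
    n <- 5
    conn <- data.frame(pre = c(1, 2, 3, 1, 4), post = c(2, 3, 4, 3, 5),
                       weight = round(runif(5, -0.8, 0.8), 3))
    inputs <- c(1L, 2L)
    spikes <- matrix(sample(c(-1L, 0L, 1L), 2 * 30, replace = TRUE,
                            prob = c(0.15, 0.35, 0.5)), 30, 2)
    params <- reservoir_params(leak = 0.5, stdp_rate = 0.01,
                               refractory_steps = 1)
    model <- toy_model(n, conn, inputs, params)
    sts <- toy_spike_trains(list(spikes))
    trained <- train_stdp(model, sts, order_seed = 1, record_events = TRUE)
    ref <- oracle_lif(n, conn, inputs, spikes, 0.5, 0.5, 1, 0.01)
    expect_equal(trained$model$weight, ref$weights, tolerance = 1e-12)
    expect_equal(trained$log$trans_counts, ref$trans, tolerance = 0)
    if (nrow(ref$events) > 0) {
      # event sets are compared after sorting; within-step emission order
      # is an implementation detail
      ev <- as.matrix(trained$log$events[, c("step", "pre", "post")])
      o1 <- order(ev[, 1], ev[, 2], ev[, 3])
      o2 <- order(ref$events[, 1], ref$events[, 2], ref$events[, 3])
      expect_equal(ev[o1, ], ref$events[o2, ], ignore_attr = TRUE)
    }
  }
})

test_that("STDP changes magnitudes only, never the topology", {
  d <- generate_cohort(cohort_config(
    n_per_group = c(HC = 3, Remitter = 3, Maintained = 3), seed = 5))
  tn <- normalize_series(interpolate_linear(d, 40))
  enc <- encode_threshold(tn)
  grid <- neuron_grid(c(4, 4, 4))
  model <- init_small_world(grid, reservoir_params(), seed = 2)
  model <- set_input_mapping(model, input_sites(grid, 23))
  trained <- train_stdp(model, enc, order_seed = 3)$model
  expect_identical(trained$pre, model$pre)
  expect_identical(trained$post, model$post)
  expect_equal(sign(trained$weight[trained$weight != 0]),
               sign(model$weight[trained$weight != 0]))
})

test_that("adding input spikes never reduces firing in excitatory nets", {
  set.seed(41)
  conn <- data.frame(pre = c(1, 2, 3), post = c(2, 3, 4), weight = 0.6)
  model <- toy_model(4, conn, c(1L, 2L),
                     reservoir_params(leak = 0, inhibitory_fraction = 0,
                                      refractory_steps = 0))
  for (rep in 1:10) {
    base <- matrix(ifelse(runif(40) < 0.3, 1L, 0L), 20, 2)
    extra <- base
    extra[sample(which(base == 0L), 3)] <- 1L
    f1 <- sum(simulate_lif(model, base))
    f2 <- sum(simulate_lif(model, extra))
    expect_gte(f2, f1)
  }
})

test_that("connectivity summaries match hand arithmetic", {
  conn <- data.frame(pre = c(1, 1, 2, 3, 4, 5), post = c(2, 3, 3, 4, 5, 6),
                     weight = c(0.5, -0.25, 1, 0.75, -0.5, 0.1))
  model <- toy_model(6, conn, c(1L, 4L), reservoir_params())
  s <- summarize_connectivity(model)
  expect_equal(s$W_a, mean(abs(conn$weight)))
  expect_equal(nrow(s$per_variable), 2)
  # all weights equal -> W_a equals that weight
  conn2 <- conn; conn2$weight <- 0.5
  expect_equal(summarize_connectivity(toy_model(6, conn2, c(1L, 4L),
                                                reservoir_params()))$W_a, 0.5)
  empty <- toy_model(2, data.frame(pre = integer(0), post = integer(0),
                                   weight = numeric(0)), 1L,
                     reservoir_params())
  expect_error(summarize_connectivity(empty), "no connections")
})

test_that("model archives round-trip losslessly", {
  grid <- neuron_grid(c(4, 4, 4))
  model <- init_small_world(grid, reservoir_params(), seed = 9)
  model <- set_input_mapping(model, input_sites(grid, 10))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  m2 <- read_model(path)
  expect_identical(m2$weight, model$weight)
  expect_identical(m2$pre, model$pre)
  expect_identical(m2$post, model$post)
  expect_identical(m2$input_mapping, unname(model$input_mapping))
  expect_equal(m2$params, model$params)
  expect_equal(m2$grid$dims, model$grid$dims)
})
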