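test_that("variable catalogue has the study's structure", {
  cat <- variable_catalog()
  expect_equal(nrow(cat), 23)
  expect_equal(cat$variable_id, 1:23)
  counts <- table(cat$instrument)
  expect_equal(unname(counts[c("BACS", "HiSoC", "SNK", "PC", "CPT")]),
               c(9, 4, 6, 3, 1), ignore_attr = TRUE)
})

test_that("default profiles encode the intended group structure", {
  p <- default_profiles()
  # coupling ordering drives the interaction analysis
  expect_lt(p$HC$coupling_strength, p$Remitter$coupling_strength)
  expect_lt(p$Remitter$coupling_strength, p$Maintained$coupling_strength)
  # HC scores at or above the other groups at baseline
  expect_true(all(p$HC$baseline_mean >= p$Remitter$baseline_mean))
  expect_true(all(p$HC$baseline_mean >= p$Maintained$baseline_mean))
  # Remitter reaches the HC level by month 24 (5th visit), per variable
  hc24 <- profile_mean_curve(p$HC, 5)[, 5]
  rem24 <- profile_mean_curve(p$Remitter, 5)[, 5]
  expect_true(all(abs(rem24 - hc24) <= 0.25))
  # Maintained trajectory is flat
  expect_true(all(abs(p$Maintained$visit_deltas) <= 0.05))
})

test_that("profile constructor validates its inputs", {
  expect_error(group_profile("HC", 0, 0, 1, -0.1, 0.1), "coupling")
  expect_error(group_profile("HC", 0, 0, 1, 1, 0), "noise_sd")
  expect_error(group_profile("HC", rep(0, 5), 0, 1, 1, 0.1), "length")
})

test_that("cohort generation is deterministic and complete", {
  cfg <- cohort_config(n_per_group = c(HC = 6, Remitter = 5, Maintained = 4),
                       seed = 7)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(d1$values, d2$values)
  expect_false(anyNA(d1$values))
  expect_equal(dim(d1$values), c(15, 23, 5))
  expect_equal(as.integer(table(d1$group)), c(6, 5, 4))
  d3 <- generate_cohort(cohort_config(
    n_per_group = c(HC = 6, Remitter = 5, Maintained = 4), seed = 8))
  expect_false(identical(d1$values, d3$values))
})

test_that("degenerate noise and coupling collapse subjects onto the mean curve", {
  quiet <- lapply(default_profiles(), function(p) {
    p$noise_sd <- rep(1e-12, 23); p$coupling_strength <- 0; p
  })
  cfg <- cohort_config(n_per_group = c(HC = 3, Remitter = 3, Maintained = 3),
                       seed = 1, profiles = quiet)
  d <- generate_cohort(cfg)
  for (g in levels(d$group)) {
    vals <- d$values[d$group == g, , , drop = FALSE]
    mc <- profile_mean_curve(quiet[[g]], 5)
    for (s in seq_len(dim(vals)[1]))
      expect_equal(vals[s, , ], mc, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("sample group means recover the closed-form mean curve", {
  # law of large numbers against the generator's own expectation
  cfg <- cohort_config(n_per_group = c(HC = 2000, Remitter = 2000,
                                       Maintained = 2000), seed = 42)
  d <- generate_cohort(cfg)
  profs <- default_profiles()
  for (g in levels(d$group)) {
    p <- profs[[g]]
    vals <- d$values[d$group == g, , , drop = FALSE]
    n <- dim(vals)[1]
    mc <- profile_mean_curve(p, 5)
    # per-visit SD of a subject's value around the mean curve
    for (k in c(1, 3, 5)) {
      lat_var <- (k - 1) * p$coupling_strength^2 * p$latent_loadings^2
      se <- sqrt(lat_var + p$noise_sd^2) / sqrt(n)
      dev <- abs(colMeans(vals[, , k]) - mc[, k])
      expect_true(all(dev <= 3.5 * se + 1e-12),
                  info = paste("group", g, "visit", k))
    }
  }
})

test_that("residual cross-variable correlation increases with coupling", {
  mean_abs_cor <- function(coupling) {
    profs <- default_profiles()
    p <- profs$HC
    p$coupling_strength <- coupling
    p$noise_sd <- rep(0.3, 23)
    cfg <- cohort_config(n_per_group = c(HC = 500, Remitter = 1,
                                         Maintained = 1),
                         seed = 99, profiles = list(
                           HC = p, Remitter = profs$Remitter,
                           Maintained = profs$Maintained))
    d <- generate_cohort(cfg)
    vals <- d$values[d$group == "HC", , ]
    resid <- sapply(1:5, function(k) sweep(vals[, , k], 2,
                                           colMeans(vals[, , k])),
                    simplify = "array")
    flat <- apply(resid, 2, as.vector)  # (subj*visit) x variable
    cm <- abs(cor(flat))
    mean(cm[upper.tri(cm)])
  }
  r <- vapply(c(0, 0.5, 1), mean_abs_cor, numeric(1))
  expect_lt(r[1], r[2])
  expect_lt(r[2], r[3])
})

test_that("cohort CSV round trip is lossless and validated", {
  cfg <- cohort_config(n_per_group = c(HC = 4, Remitter = 3, Maintained = 2),
                       seed = 3)
  d <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path)
  d2 <- read_cohort(path)
  expect_identical(unname(d2$values), unname(d$values))
  expect_equal(d2$subject_id, d$subject_id)
  expect_equal(as.character(d2$group), as.character(d$group))

  # identical file bytes on rewrite (determinism of the export)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))

  # a missing visit month is rejected, naming the subject
  long <- read.csv(path, stringsAsFactors = FALSE)
  drop <- !(long$subject_id == d$subject_id[1] & long$month == 18 &
              long$variable_id == 5)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(long[drop, ], bad, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(bad), d$subject_id[1])

  # duplicated key is rejected
  dup <- withr::local_tempfile(fileext = ".csv")
  write.csv(rbind(long, long[1, ]), dup, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(dup), "duplicate")

  # unknown group label is rejected with a row number
  long2 <- long
  long2$group[3] <- "Converter"
  badg <- withr::local_tempfile(fileext = ".csv")
  write.csv(long2, badg, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(badg), "Converter")
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_per_group = c(HC = 0, Remitter = 1,
                                             Maintained = 1)), "> 0")
  expect_error(cohort_config(visit_months = c(0, 6, 6, 18, 24)),
               "increasing")
  expect_error(cohort_config(visit_months = c(3, 6, 12, 18, 24)), "first")
})
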