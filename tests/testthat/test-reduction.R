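test_that("pattern enumeration partitions rows and respects the 2^6 bound", {
  tb <- complete_toy_table(seed = 16, n = 20)
  pats <- enumerate_patterns(tb)
  expect_length(pats, 1)
  expect_setequal(pats[[1]]$observed_roles,
                  c("mother", "father", "mgm", "mgf", "pgm", "pgf"))

  cohort <- simulate_family_data(tiny_config(seed = 17, n = 300))
  pats <- enumerate_patterns(cohort)
  expect_lte(length(pats), 64)
  rows <- sort(unlist(lapply(pats, function(p) p$row_ids)))
  expect_identical(rows, 1:300) # partition
  for (p in pats) {
    expect_true(all(p$row_ids %in% p$pool_ids)) # pool is a superset
    expect_gte(p$training_pool_size, length(p$row_ids))
  }
})

test_that("training pools follow the complete-on-subset rule on toy masks", {
  base <- complete_toy_table(seed = 18, n = 5)$values
  v <- base
  v[1:3, "father"] <- NA
  v[4:5, "father"] <- NA
  v[4:5, "mgf"] <- NA
  pats <- enumerate_patterns(make_table(v))
  expect_length(pats, 2)
  by_n <- pats[order(vapply(pats, function(p) length(p$observed_roles), numeric(1)))]
  # sparser pattern (father+mgf missing): every row is complete on its roles
  expect_equal(sort(by_n[[1]]$pool_ids), 1:5)
  # richer pattern (only father missing): rows 4-5 lack mgf, excluded
  expect_equal(sort(by_n[[2]]$pool_ids), 1:3)
})

test_that("a single-pattern reduction equals a plain 80/20 fit-and-score", {
  tb <- complete_toy_table(seed = 19, n = 50)
  red <- reduction_fit(tb, "linear", seed = 9)
  expect_length(red$per_pattern_mse, 1)
  # reproduce the documented substream split by hand and fit directly
  set.seed(derive_seed(9, 303L, 1L))
  perm <- sample(1:50)
  train <- perm[1:40]
  test <- perm[41:50]
  fit <- linear_fit(tb$values[train, -1], tb$values[train, "child"])
  mse <- mean((predict(fit, tb$values[test, -1]) - tb$values[test, "child"])^2)
  expect_equal(unname(red$per_pattern_mse), mse, tolerance = 1e-12)
  expect_equal(red$mse_sd, 0)
})

test_that("per-pattern linear mse matches hand-solved least squares on a toy table", {
  base <- complete_toy_table(seed = 20, n = 40)$values
  v <- base
  v[21:40, c("mgm", "mgf", "pgm", "pgf")] <- NA # pattern B: parents only
  tb <- make_table(v)
  red <- reduction_fit(tb, "linear", seed = 11, min_train = 4)
  expect_length(red$per_pattern_mse, 2)
  pats <- enumerate_patterns(tb)
  for (pi in seq_along(pats)) {
    pat <- pats[[pi]]
    pool <- pat$pool_ids
    set.seed(derive_seed(11, 303L, pi))
    perm <- sample(pool)
    ntr <- floor(0.8 * length(pool))
    train <- perm[seq_len(ntr)]
    test <- perm[(ntr + 1):length(pool)]
    b <- normal_equations(v[train, pat$observed_roles], v[train, "child"])
    pred <- drop(cbind(1, v[test, pat$observed_roles, drop = FALSE]) %*% b)
    mse <- mean((pred - v[test, "child"])^2)
    expect_equal(unname(red$per_pattern_mse[[pat$key]]), mse, tolerance = 1e-10)
  }
})

test_that("small-pool patterns are skipped with a warning, not silently dropped", {
  base <- complete_toy_table(seed = 21, n = 30)$values
  v <- base
  v[1:28, "pgf"] <- NA # pgf-observed pattern has a 2-row pool
  expect_warning(red <- reduction_fit(make_table(v), "linear", seed = 3),
                 "skipped")
  expect_length(red$per_pattern_mse, 1)
  expect_length(red$skipped, 1)
})

test_that("prediction routes rows to their exact pattern's model", {
  cohort <- simulate_family_data(tiny_config(seed = 22, n = 400))
  suppressWarnings(red <- reduction_fit(cohort, "linear", seed = 5))
  vals <- cohort$values
  checked <- 0
  for (i in seq_len(100)) {
    row <- vals[i, ]
    obs <- names(row[-1])[!is.na(row[-1])]
    # brute-force matcher over fitted patterns
    entry <- NULL
    for (f in red$fitted) {
      if (setequal(f$pattern$observed_roles, obs)) entry <- f
    }
    if (is.null(entry)) {
      expect_error(reduction_predict(red, row), "pattern")
    } else {
      manual <- drop(predict(entry$model,
                             matrix(row[entry$pattern$observed_roles], 1)))
      expect_equal(reduction_predict(red, row), manual, tolerance = 1e-12)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("a complete new row on a complete-data fit equals the model's prediction", {
  tb <- complete_toy_table(seed = 23, n = 60)
  red <- reduction_fit(tb, "linear", seed = 7)
  row <- tb$values[1, ]
  fit <- red$fitted[[1]]$model
  expect_equal(reduction_predict(red, row),
               drop(predict(fit, matrix(row[-1], 1))), tolerance = 1e-12)
  only_mother <- row
  only_mother[c("father", "mgm", "mgf", "pgm", "pgf")] <- NA
  expect_error(reduction_predict(red, only_mother), "coarser|pattern")
})

test_that("with zero missingness the reduction mse approximates the noise variance", {
  mses <- vapply(1:20, function(s) {
    cfg <- linear_config(seed = 700 + s, n = 500, noise_sd = 1.0,
                         missing_rates = rep(0, 7))
    tb <- generate_families(cfg)
    reduction_fit(tb, "linear", seed = s)$mse_mean
  }, numeric(1))
  expect_gt(mean(mses), 0.8)
  expect_lt(mean(mses), 1.3)
})

test_that("reduction reports serialize with readable pattern masks", {
  cohort <- simulate_family_data(tiny_config(seed = 24, n = 300))
  suppressWarnings(red <- reduction_fit(cohort, "linear", seed = 2))
  path <- tempfile(fileext = ".csv")
  write_reduction_csv(red, path)
  df <- read.csv(path)
  expect_equal(nrow(df), length(red$per_pattern_mse))
  expect_true(all(grepl("^child,", df$pattern)))
})
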