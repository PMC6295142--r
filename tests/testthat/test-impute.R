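masked_fixture <- function(seed = 21, n = 120) {
  simulate_family_data(tiny_config(seed = seed, n = n))
}

test_that("mean initialization fills by observed column means only", {
  tb <- complete_toy_table(seed = 1, n = 10)
  expect_identical(mean_initialize(tb)$values, tb$values)

  v <- tb$values[1:3, ]
  v[, "mother"] <- c(20, 24, NA)
  out <- mean_initialize(make_table(v))
  expect_equal(unname(out$values[3, "mother"]), 22)
  expect_equal(out$values[, -2], v[, -2]) # untouched elsewhere

  v[, "mother"] <- NA
  expect_error(mean_initialize(make_table(v)), "mother")
})

test_that("iterative PCA recovers a rank-1 completion to 1e-8", {
  u <- c(1, 2, 3, 4, 5, 6, 7, 8)
  v <- c(2, -1, 0.5)
  M <- outer(u, v)
  X <- M
  X[3, 2] <- NA
  out <- iterative_pca_impute(X, ncp = 1, regularized = FALSE,
                              center = FALSE, scale = FALSE,
                              tol = 1e-14, max_iter = 5000)
  expect_equal(out[3, 2], M[3, 2], tolerance = 1e-8)
  expect_equal(out[!is.na(X)], M[!is.na(X)]) # observed untouched
})

test_that("iterative PCA leaves complete tables unchanged", {
  tb <- complete_toy_table(seed = 2, n = 20)
  out <- iterative_pca_impute(tb)
  expect_identical(out$values, tb$values)
})

test_that("regularization is a no-op when the discarded spectrum is zero", {
  # exact rank-1 after centering is impossible to arrange with scaling, so
  # work on the raw scale where the discarded singular values vanish
  u <- rnorm(12)
  M <- outer(u, c(1, 2, 3, 4, 5))
  X <- M
  X[c(2, 18, 40)] <- NA
  a <- iterative_pca_impute(X, ncp = 1, regularized = FALSE,
                            center = FALSE, scale = FALSE, tol = 1e-13)
  b <- iterative_pca_impute(X, ncp = 1, regularized = TRUE,
                            center = FALSE, scale = FALSE, tol = 1e-13)
  expect_equal(a, b, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the observed-cell reconstruction error is non-increasing over sweeps", {
  set.seed(31)
  M <- tcrossprod(matrix(rnorm(60), 20, 3), matrix(rnorm(15), 5, 3)) +
    matrix(rnorm(100, 0, 0.3), 20, 5)
  X <- M
  X[sample(length(X), 25)] <- NA
  errs <- vapply(1:12, function(k) {
    out <- suppressWarnings( # iteration caps below convergence, by design
      iterative_pca_impute(X, ncp = 2, regularized = FALSE,
                           center = FALSE, scale = FALSE,
                           tol = 1e-300, max_iter = k))
    attr(out, "pca_resid_var")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("multiple PCA imputation adds noise only at missing cells, reproducibly", {
  tb <- masked_fixture()
  cfg <- imputation_config("pca", m = 10, seed = 5)
  stack <- mipca(tb, cfg)
  expect_length(stack$datasets, 10)
  obs <- tb$mask
  for (d in stack$datasets) {
    expect_true(is_complete(d))
    expect_identical(d$values[obs], tb$values[obs])
  }
  stack2 <- mipca(tb, cfg)
  expect_identical(stack$datasets, stack2$datasets)
})

test_that("with an exactly low-rank table the PCA imputation noise vanishes", {
  # two-factor structure collapses to rank 1 after column centering, so the
  # residual variance driving the between-dataset noise is zero
  u <- seq(1, 3, length.out = 15)
  M <- outer(rep(1, 15), c(15, 25, 27, 27, 27, 27, 27)) +
    outer(u - mean(u), c(1, 0.5, 2, 1.5, 1, 0.8, 0.6))
  X <- M
  X[cbind(c(2, 5, 9), c(3, 5, 7))] <- NA
  tb <- make_table(X)
  point <- iterative_pca_impute(tb, ncp = 2, regularized = TRUE, tol = 1e-13)
  stack <- mipca(tb, imputation_config("pca", m = 3, ncp = 2, seed = 9, tol = 1e-13))
  expect_lt(attr(point, "pca_resid_var"), 1e-12)
  for (d in stack$datasets) {
    expect_equal(d$values, point$values, tolerance = 1e-5)
  }
})

test_that("the Bayesian regression draw collapses to least squares with zero residuals", {
  z <- c(1, 2, 3)
  X <- cbind(1, c(0, 1, 2))
  d <- norm_draw(z, X)
  expect_equal(unname(d$beta_hat), c(1, 1))
  expect_identical(d$beta_star, d$beta_hat)
  expect_equal(d$sigma_star2, 0)
  expect_error(norm_draw(c(1, 2), cbind(1, c(0, 1))), "observed rows")
})

test_that("the posterior draw is centred on the least-squares estimate", {
  set.seed(11)
  x <- rnorm(30)
  z <- 2 + 0.5 * x + rnorm(30)
  X <- cbind(1, x)
  bh <- norm_draw(z, X)$beta_hat
  draws <- t(replicate(4000, norm_draw(z, X)$beta_star))
  mc_se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - bh) < 4 * mc_se))
})

test_that("NORM imputation hits the truth in the noiseless limit and has the right spread", {
  x <- seq(0, 1, length.out = 20)
  z_true <- 3 + 2 * x
  z <- z_true
  z[c(4, 11)] <- NA
  X <- cbind(1, x)
  set.seed(1)
  imp <- norm_impute_univariate(z, X)
  expect_equal(imp, z_true[c(4, 11)], tolerance = 1e-10)
  expect_length(norm_impute_univariate(z_true, X), 0)

  # predictive variance: intercept-only model, one missing cell
  set.seed(2)
  nz <- 50
  zz <- c(rnorm(nz, 10, 2), NA)
  D <- matrix(1, nz + 1, 1)
  sims <- replicate(10000, {
    imp <- norm_impute_univariate(zz, D)
    s2 <- norm_draw(zz[1:nz], D[1:nz, , drop = FALSE])$sigma_star2
    c(imp, s2)
  })
  ratio <- var(sims[1, ]) / (mean(sims[2, ]) * (1 + 1 / nz))
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("PMM with q = 1 matches an exhaustive nearest-donor search", {
  set.seed(3)
  x <- rnorm(25)
  z <- 1 + x + rnorm(25, 0, 0.5)
  z[c(3, 17, 22)] <- NA
  X <- cbind(1, x)
  obs <- !is.na(z)
  bh <- normal_equations(x[obs], z[obs])
  fitted_obs <- drop(cbind(1, x[obs]) %*% bh)
  fitted_mis <- drop(cbind(1, x[!obs]) %*% bh)
  oracle <- vapply(fitted_mis, function(fm) {
    z[obs][which.min(abs(fitted_obs - fm))]
  }, numeric(1))
  set.seed(4)
  imp <- pmm_impute_univariate(z, X, q = 1, beta_star = bh)
  expect_equal(imp, oracle)
})

test_that("PMM with q = nz picks donors uniformly and stays in the observed support", {
  x <- c(0, 1, 2, 3, 4, 5, NA)
  z <- c(10, 11, 12, 13, 14, 15, NA)
  X <- cbind(1, c(0, 1, 2, 3, 4, 5, 2.5))
  zz <- c(z[1:6], NA)
  set.seed(5)
  draws <- replicate(6000, pmm_impute_univariate(zz, X, q = 6))
  expect_true(all(draws %in% z[1:6]))
  freq <- table(factor(draws, levels = z[1:6])) / 6000
  se <- sqrt((1 / 6) * (5 / 6) / 6000)
  expect_true(all(abs(freq - 1 / 6) < 4 * se))
  expect_error(pmm_impute_univariate(zz, X, q = 10), "donors")
})

test_that("chained equations preserve observed cells and complete every dataset", {
  tb <- masked_fixture(seed = 22)
  obs <- tb$mask
  for (method in c("mice_norm", "mice_pmm")) {
    stack <- mice_engine(tb, imputation_config(method, m = 4, seed = 6))
    expect_length(stack$datasets, 4)
    for (d in stack$datasets) {
      expect_true(is_complete(d))
      expect_identical(d$values[obs], tb$values[obs])
    }
    # PMM imputations live in the observed support of their column
    if (method == "mice_pmm") {
      for (d in stack$datasets) {
        for (j in which(colSums(!obs) > 0)) {
          expect_true(all(d$values[!obs[, j], j] %in% tb$values[obs[, j], j]))
        }
      }
    }
  }
})

test_that("a complete table passes through the chained-equations engine unchanged", {
  tb <- complete_toy_table(seed = 23, n = 20)
  stack <- mice_engine(tb, imputation_config("mice_norm", m = 3, seed = 7))
  for (d in stack$datasets) expect_identical(d$values, tb$values)
})

test_that("a single incomplete column is stationary after the first cycle", {
  # with one incomplete column every cycle re-imputes from the same observed
  # predictors, so cycle 1 and cycle 10 agree in distribution
  tb0 <- complete_toy_table(seed = 24, n = 150)
  v <- tb0$values
  v[1:40, "father"] <- NA
  tb <- make_table(v)
  get_means <- function(iters, seed) {
    stack <- mice_engine(tb, imputation_config("mice_norm", m = 30,
                                               mice_iterations = iters,
                                               seed = seed))
    vapply(stack$datasets, function(d) mean(d$values[1:40, "father"]), numeric(1))
  }
  m1 <- get_means(1, 100)
  m10 <- get_means(10, 200)
  pooled_se <- sqrt(var(m1) / 30 + var(m10) / 30)
  expect_lt(abs(mean(m1) - mean(m10)), 4 * pooled_se)
})

test_that("the chained-equations engine reports unusable columns", {
  tb0 <- complete_toy_table(seed = 25, n = 12)
  v <- tb0$values
  v[1:6, "pgf"] <- NA # only 6 observed rows against 8 parameters
  expect_error(mice_engine(make_table(v),
                           imputation_config("mice_norm", m = 1, seed = 1)),
               "pgf")
})

test_that("imputed stacks round-trip to CSV files with a provenance sidecar", {
  tb <- masked_fixture(seed = 26, n = 40)
  stack <- impute_families(tb, imputation_config("mice_pmm", m = 2, seed = 8))
  dir <- tempfile()
  write_imputed_stack(stack, dir)
  expect_true(file.exists(file.path(dir, "imputed_01.csv")))
  expect_true(file.exists(file.path(dir, "imputed_02.csv")))
  prov <- readLines(file.path(dir, "provenance.txt"))
  expect_true(any(grepl("^method: mice_pmm", prov)))
  back <- read_family_csv(file.path(dir, "imputed_01.csv"))
  expect_equal(back$values, stack$datasets[[1]]$values, tolerance = 1e-10)
})
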