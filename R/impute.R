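#' Multiple-imputation configuration
#'
#' @param method one of `"pca"` (iterative principal-component imputation
#'   with Gaussian residual noise), `"mice_norm"` (chained equations,
#'   Bayesian linear regression) or `"mice_pmm"` (chained equations,
#'   predictive mean matching).
#' @param m number of imputed datasets (default 10).
#' @param mice_iterations cycles through the univariate models (default 10).
#' @param q PMM donor-pool size (default 3, a value that has performed well
#'   in simulation).
#' @param ncp number of principal components retained (default 2).
#' @param regularized use the regularized PCA reconstruction (default TRUE).
#' @param tol convergence threshold for iterative PCA: relative Frobenius
#'   change of the imputed cells (default 1e-6).
#' @param max_iter iteration cap for iterative PCA (default 1000).
#' @param seed integer seed; all chains/datasets derive substreams from it.
#' @return an `imputation_config` list.
#' @export
imputation_config <- function(method = c("pca", "mice_norm", "mice_pmm"),
                              m = 10, mice_iterations = 10, q = 3,
                              ncp = 2, regularized = TRUE,
                              tol = 1e-6, max_iter = 1000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(m >= 1, q >= 1, ncp >= 1, ncp < 7, tol > 0, mice_iterations >= 1,
            max_iter >= 1)
  structure(list(method = method, m = as.integer(m),
                 mice_iterations = as.integer(mice_iterations),
                 q = as.integer(q), ncp = as.integer(ncp),
                 regularized = isTRUE(regularized), tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "imputation_config")
}

#' Replace missing cells by observed column means
#'
#' The starting point for both the iterative-PCA sweep and each chained
#' equations chain.
#'
#' @param table a `family_table`.
#' @return a complete `family_table`; `imputed` marks the filled cells.
#' @export
mean_initialize <- function(table) {
  stopifnot(inherits(table, "family_table"))
  vals <- table$values
  miss <- !table$mask
  for (j in seq_len(ncol(vals))) {
    if (any(miss[, j])) {
      obs <- vals[!miss[, j], j]
      if (length(obs) == 0L) {
        stop("column '", FAMILY_ROLES[j], "' has no observed values; cannot initialize")
      }
      vals[miss[, j], j] <- mean(obs)
    }
  }
  family_table(vals, truth = table$truth, imputed = miss)
}

# Core iterative-PCA completion on a plain matrix. `miss` marks cells to fill.
# Alternates (optionally centered/scaled) rank-ncp SVD reconstruction with
# overwriting the missing cells, until the relative Frobenius change of the
# imputed cells drops below tol. The regularized variant shrinks each retained
# singular value d by (d^2 - n*sigma2)/d with sigma2 the mean of the discarded
# squared singular values divided by n (clipped at zero).
pca_complete_matrix <- function(x, miss, ncp, regularized = TRUE,
                                center = TRUE, scale = TRUE,
                                tol = 1e-6, max_iter = 1000) {
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(ncp >= 1, ncp < p)
  X <- x
  last_change <- 0
  converged <- !any(miss)
  iters <- 0L
  resid_var <- 0
  for (it in seq_len(max_iter)) {
    mu <- if (center) colMeans(X) else rep(0, p)
    sc <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
    sc[!is.finite(sc) | sc < 1e-12] <- 1
    Xs <- sweep(sweep(X, 2, mu, `-`), 2, sc, `/`)
    sv <- svd(Xs)
    d <- sv$d[seq_len(ncp)]
    if (regularized && p > ncp) {
      disc2 <- mean(sv$d[(ncp + 1):p]^2)
      d <- pmax((d^2 - disc2) / d, 0)
    }
    fit_s <- sv$u[, seq_len(ncp), drop = FALSE] %*%
      (d * t(sv$v[, seq_len(ncp), drop = FALSE]))
    fitted <- sweep(sweep(fit_s, 2, sc, `*`), 2, mu, `+`)
    resid_var <- mean((fitted[!miss] - x[!miss])^2)
    iters <- it
    if (!any(miss)) {
      converged <- TRUE
      break
    }
    newX <- X
    newX[miss] <- fitted[miss]
    last_change <- sqrt(sum((newX[miss] - X[miss])^2)) /
      max(sqrt(sum(newX^2)), .Machine$double.eps)
    X <- newX
    if (last_change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("iterative PCA did not converge in ", max_iter,
            " iterations (last relative change ", format(last_change), ")")
  }
  list(completed = X, iterations = iters, converged = converged,
       last_change = last_change, resid_var = resid_var)
}

#' Iterative PCA single imputation
#'
#' Fills missing cells by alternating a low-rank SVD reconstruction with
#' re-imputation until convergence, starting from observed column means.
#' Columns are standardized before each SVD by default (all seven columns are
#' BMI, but standardization is robust to variance imbalance); set
#' `center = scale = FALSE` for raw low-rank completion. Observed cells are
#' never altered.
#'
#' @param x a `family_table` or a plain numeric matrix with `NA` for missing.
#' @param ncp number of components (default 2).
#' @param regularized shrink retained singular values by the mean discarded
#'   spectrum (default TRUE; prevents over-fitting with many missing cells).
#' @param center,scale standardize columns before the SVD (defaults TRUE).
#' @param tol,max_iter convergence control.
#' @return a complete object of the same kind as `x`; attribute
#'   `pca_resid_var` holds the mean squared reconstruction residual over
#'   observed cells (original scale), `pca_iterations` the sweep count.
#' @export
iterative_pca_impute <- function(x, ncp = 2, regularized = TRUE,
                                 center = TRUE, scale = TRUE,
                                 tol = 1e-6, max_iter = 1000) {
  if (inherits(x, "family_table")) {
    miss <- !x$mask
    n_obs_col <- colSums(x$mask)
    if (any(n_obs_col < 2)) {
      stop("column '", FAMILY_ROLES[which(n_obs_col < 2)[1]],
           "' has fewer than 2 observed values")
    }
    start <- mean_initialize(x)
    res <- pca_complete_matrix(start$values, miss, ncp, regularized,
                               center, scale, tol, max_iter)
    out <- family_table(res$completed, truth = x$truth, imputed = miss)
    attr(out, "pca_resid_var") <- res$resid_var
    attr(out, "pca_iterations") <- res$iterations
    out
  } else {
    x <- as.matrix(x)
    miss <- is.na(x)
    start <- x
    for (j in seq_len(ncol(x))) {
      if (any(miss[, j])) start[miss[, j], j] <- mean(x[!miss[, j], j])
    }
    res <- pca_complete_matrix(start, miss, ncp, regularized,
                               center, scale, tol, max_iter)
    out <- res$completed
    attr(out, "pca_resid_var") <- res$resid_var
    attr(out, "pca_iterations") <- res$iterations
    out
  }
}

#' Multiple imputation by iterative PCA
#'
#' Runs the iterative-PCA point imputation once, then builds `m` completed
#' datasets by adding independent Gaussian noise — variance equal to the mean
#' squared reconstruction residual over observed cells — to the imputed (not
#' the observed) cells. A simplified stand-in for full bootstrap-based
#' multiple imputation from PCA; see the methods vignette.
#'
#' @param table a masked `family_table`.
#' @param config an `imputation_config` with `method = "pca"`.
#' @return an `imputed_stack` of `config$m` complete tables.
#' @export
mipca <- function(table, config) {
  stopifnot(inherits(table, "family_table"), inherits(config, "imputation_config"))
  point <- iterative_pca_impute(table, ncp = config$ncp,
                                regularized = config$regularized,
                                tol = config$tol, max_iter = config$max_iter)
  sigma <- sqrt(attr(point, "pca_resid_var"))
  miss <- !table$mask
  seeds <- vapply(seq_len(config$m), function(j) derive_seed(config$seed, 101L, j),
                  integer(1))
  datasets <- lapply(seq_len(config$m), function(j) {
    set.seed(seeds[j])
    vals <- point$values
    vals[miss] <- vals[miss] + stats::rnorm(sum(miss), 0, sigma)
    family_table(vals, truth = table$truth, imputed = miss)
  })
  imputed_stack(datasets, config, seeds)
}

#' One proper Bayesian linear-regression draw
#'
#' Given the observed responses `z_obs` and their design matrix (intercept
#' included), computes the least-squares fit and draws `sigma*^2` from its
#' scaled inverse chi-square posterior, then `beta*` from
#' `MVN(beta_hat, sigma*^2 (X'X)^{-1})`. With zero residual sum of squares
#' the posterior is degenerate and `beta* = beta_hat` exactly.
#'
#' @param z_obs numeric vector of observed responses (length nz).
#' @param X_obs nz x k design matrix including the intercept column.
#' @return a `norm_draw` list: `beta_hat`, `V`, `beta_star`, `sigma_hat2`,
#'   `sigma_star2`, `nz`.
#' @export
norm_draw <- function(z_obs, X_obs) {
  X_obs <- as.matrix(X_obs)
  nz <- length(z_obs)
  k <- ncol(X_obs)
  if (nz <= k) {
    stop("norm_draw needs more observed rows (", nz, ") than parameters (", k, ")")
  }
  qr_x <- qr(X_obs)
  if (qr_x$rank < k) {
    bad <- colnames(X_obs)[qr_x$pivot[(qr_x$rank + 1):k]]
    if (is.null(bad)) bad <- qr_x$pivot[(qr_x$rank + 1):k]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta_hat <- qr.coef(qr_x, z_obs)
  rss <- sum(qr.resid(qr_x, z_obs)^2)
  df <- nz - k
  sigma_hat2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  if (rss <= 1e-12 * max(1, sum(z_obs^2))) {
    sigma_star2 <- 0
    beta_star <- beta_hat
    V <- matrix(0, k, k)
  } else {
    sigma_star2 <- rss / stats::rchisq(1, df)
    V <- sigma_star2 * xtx_inv
    beta_star <- drop(beta_hat + t(chol(V)) %*% stats::rnorm(k))
  }
  structure(list(beta_hat = beta_hat, V = V, beta_star = beta_star,
                 sigma_hat2 = sigma_hat2, sigma_star2 = sigma_star2, nz = nz),
            class = "norm_draw")
}

#' Univariate imputation by Bayesian linear regression (NORM)
#'
#' Missing entries of `z` are drawn from the posterior predictive
#' distribution: `beta* x_i + N(0, sigma*^2)` with `beta*`, `sigma*^2` one
#' proper draw from [norm_draw()] on the observed rows. Uses the session RNG
#' stream; seed upstream for reproducibility.
#'
#' @param z numeric vector with `NA` at the entries to impute.
#' @param X design matrix (intercept included), one row per entry of `z`.
#' @return numeric vector of imputed values, one per missing position (in
#'   row order); empty if nothing is missing.
#' @export
norm_impute_univariate <- function(z, X) {
  X <- as.matrix(X)
  obs <- !is.na(z)
  if (all(obs)) return(numeric(0))
  draw <- norm_draw(z[obs], X[obs, , drop = FALSE])
  mu <- drop(X[!obs, , drop = FALSE] %*% draw$beta_star)
  mu + stats::rnorm(length(mu), 0, sqrt(draw$sigma_star2))
}

#' Univariate imputation by predictive mean matching (PMM)
#'
#' For each missing entry, the `q` observed donors whose least-squares fitted
#' values `beta_hat x_h` are closest to the target's perturbed fitted value
#' `beta* x_i` are identified (ties broken by lowest row index), one donor is
#' chosen uniformly at random, and its observed `z` becomes the imputation —
#' so every imputed value lies in the observed support of `z`.
#'
#' @param z numeric vector with `NA` at the entries to impute.
#' @param X design matrix (intercept included), one row per entry of `z`.
#' @param q donor-pool size (default 3).
#' @param beta_star optional override of the perturbed coefficient vector
#'   (used by tests to pin `beta* = beta_hat`).
#' @return numeric vector of imputed values, one per missing position.
#' @export
pmm_impute_univariate <- function(z, X, q = 3, beta_star = NULL) {
  X <- as.matrix(X)
  obs <- !is.na(z)
  nz <- sum(obs)
  if (all(obs)) return(numeric(0))
  if (nz < q) stop("PMM needs at least q = ", q, " observed donors, have ", nz)
  draw <- norm_draw(z[obs], X[obs, , drop = FALSE])
  if (is.null(beta_star)) beta_star <- draw$beta_star
  fitted_obs <- drop(X[obs, , drop = FALSE] %*% draw$beta_hat)
  fitted_mis <- drop(X[!obs, , drop = FALSE] %*% beta_star)
  z_obs <- z[obs]
  vapply(fitted_mis, function(fm) {
    pool <- order(abs(fitted_obs - fm))[seq_len(q)] # stable: ties to lowest index
    z_obs[pool[sample.int(q, 1L)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations
#'
#' Fully conditional specification: each chain starts from observed column
#' means, then cycles through the incomplete columns (visited in ascending
#' missing-fraction order), re-imputing each column's missing cells from all
#' other columns' current completed values with the configured univariate
#' model (NORM or PMM). The `m` chains are independent; observed cells are
#' never altered.
#'
#' @param table a masked `family_table`.
#' @param config an `imputation_config` with method `"mice_norm"` or
#'   `"mice_pmm"`.
#' @return an `imputed_stack` of `config$m` complete tables.
#' @export
mice_engine <- function(table, config) {
  stopifnot(inherits(table, "family_table"), inherits(config, "imputation_config"))
  if (!config$method %in% c("mice_norm", "mice_pmm")) {
    stop("mice_engine requires method 'mice_norm' or 'mice_pmm'")
  }
  miss <- !table$mask
  frac <- colMeans(miss)
  incomplete <- which(frac > 0)
  visit <- incomplete[order(frac[incomplete])]
  k <- 7L # intercept + 6 predictors
  for (j in incomplete) {
    if (sum(!miss[, j]) < k + 1L) {
      stop("column '", FAMILY_ROLES[j], "' has too few observed rows (",
           sum(!miss[, j]), ") for a ", k, "-parameter imputation model")
    }
  }
  seeds <- vapply(seq_len(config$m), function(ch) derive_seed(config$seed, 202L, ch),
                  integer(1))
  datasets <- lapply(seq_len(config$m), function(ch) {
    set.seed(seeds[ch])
    X <- mean_initialize(table)$values
    if (length(visit) > 0) {
      for (it in seq_len(config$mice_iterations)) {
        for (j in visit) {
          z <- table$values[, j] # NA at missing
          design <- cbind(1, X[, -j, drop = FALSE])
          imp <- if (config$method == "mice_norm") {
            norm_impute_univariate(z, design)
          } else {
            pmm_impute_univariate(z, design, q = config$q)
          }
          X[miss[, j], j] <- imp
        }
      }
    }
    family_table(X, truth = table$truth, imputed = miss)
  })
  imputed_stack(datasets, config, seeds, visit_order = FAMILY_ROLES[visit])
}

#' Impute a family table with any configured method
#'
#' Dispatches to [mipca()] or [mice_engine()] according to `config$method`.
#'
#' @param table a masked `family_table`.
#' @param config an `imputation_config`.
#' @return an `imputed_stack`.
#' @export
impute_families <- function(table, config) {
  switch(config$method,
    pca = mipca(table, config),
    mice_norm = ,
    mice_pmm = mice_engine(table, config)
  )
}

#' Container for multiply-imputed datasets
#'
#' @param datasets list of complete `family_table`s agreeing with the input
#'   on all observed cells.
#' @param config the `imputation_config` used.
#' @param seeds per-dataset substream seeds (provenance).
#' @param visit_order column visit order used by chained equations, if any.
#' @return an `imputed_stack`.
#' @export
imputed_stack <- function(datasets, config, seeds, visit_order = NULL) {
  stopifnot(length(datasets) >= 1)
  for (d in datasets) {
    if (!is_complete(d)) stop("imputed_stack datasets must be complete")
  }
  structure(list(datasets = datasets, config = config, seeds = seeds,
                 visit_order = visit_order),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("imputed_stack:", length(x$datasets), "datasets, method =",
      x$config$method, "\n")
  invisible(x)
}

#' Write an imputed stack as CSV files plus a provenance sidecar
#'
#' Dataset `j` goes to `<dir>/imputed_<j>.csv`; `<dir>/provenance.txt` records
#' the method, its parameters, the per-dataset seeds and the visit order as
#' `key: value` lines.
#'
#' @param stack an `imputed_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_along(stack$datasets)) {
    write_family_csv(stack$datasets[[j]], file.path(dir, sprintf("imputed_%02d.csv", j)))
  }
  cfg <- stack$config
  lines <- c(
    paste0("method: ", cfg$method),
    paste0("m: ", cfg$m),
    paste0("mice_iterations: ", cfg$mice_iterations),
    paste0("q: ", cfg$q),
    paste0("ncp: ", cfg$ncp),
    paste0("regularized: ", cfg$regularized),
    paste0("seed: ", cfg$seed),
    paste0("dataset_seeds: ", paste(stack$seeds, collapse = ",")),
    paste0("visit_order: ", paste(stack$visit_order, collapse = ","))
  )
  writeLines(lines, file.path(dir, "provenance.txt"))
  invisible(dir)
}
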