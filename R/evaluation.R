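fit_predict_model <- function(model_tag, X_train, y_train, X_test,
                              nn_args = list()) {
  switch(model_tag,
    linear = {
      if (ncol(X_train) == 0L) {
        rep(mean(y_train), nrow(X_test))
      } else {
        predict(linear_fit(X_train, y_train), X_test)
      }
    },
    nn = {
      if (ncol(X_train) == 0L) {
        rep(mean(y_train), nrow(X_test))
      } else {
        net <- do.call(nn_train, c(list(X = X_train, y = y_train), nn_args))
        nn_predict(net, X_test)
      }
    },
    additive = {
      fit <- do.call(additive_backfit, c(list(X = X_train, y = y_train), nn_args))
      predict(fit, X_test)
    },
    mean = rep(mean(y_train), nrow(X_test)),
    stop("unknown model_tag: ", model_tag)
  )
}

model_is_stochastic <- function(model_tag) model_tag == "nn"

#' Leave-one-out cross-validation with minimum-over-repetitions errors
#'
#' Each observation is left out in turn and predicted by a model fitted to
#' the remaining rows. Stochastic models (the neural network) are refitted
#' `reps` times per fold — each repetition on its own seed substream, with
#' repetition 1 shared across different `reps` settings — and the minimum
#' squared error over repetitions is kept per observation; deterministic
#' models collapse to a single fit. Folds whose fit fails are recorded and
#' dropped from the mse with a warning.
#'
#' @param X n x p covariate matrix.
#' @param y length-n response.
#' @param model_tag `"linear"`, `"nn"`, `"additive"` or `"mean"`.
#' @param reps repetitions per fold for stochastic models (default 3).
#' @param seed master seed for the per-fold, per-repetition substreams.
#' @param nn_args extra arguments passed to the model fitter.
#' @return a `cv_result`: `per_obs_se` (per-observation minimum squared
#'   errors, NA for failed folds), `mse`, `n_failed`, `model_tag`, `reps`.
#' @export
loo_cv <- function(X, y, model_tag = "linear", reps = 3, seed = 1,
                   nn_args = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 3)
  reps_eff <- if (model_is_stochastic(model_tag)) reps else 1L
  per_obs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    errs <- rep(NA_real_, reps_eff)
    for (r in seq_len(reps_eff)) {
      set.seed(derive_seed(seed, i, r))
      pred <- tryCatch(
        fit_predict_model(model_tag, X[-i, , drop = FALSE], y[-i],
                          X[i, , drop = FALSE], nn_args),
        error = function(e) NA_real_
      )
      errs[r] <- (pred - y[i])^2
    }
    if (any(!is.na(errs))) per_obs[i] <- min(errs, na.rm = TRUE)
  }
  n_failed <- sum(is.na(per_obs))
  if (n_failed > 0) {
    warning(n_failed, " of ", n, " leave-one-out folds failed; mse computed over the rest")
  }
  structure(list(per_obs_se = per_obs, mse = mean(per_obs, na.rm = TRUE),
                 n_failed = n_failed, model_tag = model_tag, reps = reps_eff),
            class = "cv_result")
}

#' Leave-one-out CV of a complete family table
#'
#' Child BMI is the response, the six relatives are the covariates.
#'
#' @param dataset a complete `family_table`.
#' @inheritParams loo_cv
#' @return a `cv_result`.
#' @export
loo_cv_table <- function(dataset, model_tag = "linear", reps = 3, seed = 1,
                         nn_args = list()) {
  stopifnot(inherits(dataset, "family_table"), is_complete(dataset))
  loo_cv(dataset$values[, RELATIVE_ROLES, drop = FALSE],
         dataset$values[, "child"], model_tag, reps, seed, nn_args)
}

#' Percent of response variance explained
#'
#' `100 * (1 - mse / Var(y))` with the sample (n-1) variance; negative for
#' models worse than the mean predictor (returned as-is).
#'
#' @param mse mean squared prediction error (BMI^2).
#' @param y response vector.
#' @return R^2 in percent.
#' @export
r_squared <- function(mse, y) {
  v <- stats::var(y)
  if (!is.finite(v) || v <= 0) stop("r_squared needs a response with positive variance")
  100 * (1 - mse / v)
}

#' Pool per-dataset cross-validation errors over an imputed stack
#'
#' @param mse_values per-dataset mse values (one per imputed dataset).
#' @param y the response vector (the child column, identical across
#'   datasets when the child is fully observed).
#' @param model_tag which prediction rule produced the errors.
#' @param reps repetitions used per fit.
#' @return a `cv_report`: `per_dataset_mse`, `mse_mean` (arithmetic mean),
#'   `mse_sd` (sample sd, 0 when m = 1), `r2_percent`, `model_tag`, `reps`.
#' @export
pool_mse <- function(mse_values, y, model_tag = "linear", reps = 3) {
  m <- length(mse_values)
  stopifnot(m >= 1)
  mse_mean <- mean(mse_values)
  mse_sd <- if (m > 1) stats::sd(mse_values) else 0
  structure(list(per_dataset_mse = mse_values, mse_mean = mse_mean,
                 mse_sd = mse_sd, r2_percent = r_squared(mse_mean, y),
                 model_tag = model_tag, reps = reps),
            class = "cv_report")
}

#' Combine coefficient estimates across imputed datasets by Rubin's rules
#'
#' Pooled estimate = mean of the per-dataset estimates; within variance =
#' mean squared standard error; between variance = sample variance of the
#' estimates; total variance `T = W + (1 + 1/m) B`; degrees of freedom
#' `(m - 1) (1 + W / ((1 + 1/m) B))^2`; two-sided p-value from the t
#' distribution (normal when B = 0, where df is infinite).
#'
#' @param estimates m x k matrix of per-dataset coefficient estimates
#'   (vectors are treated as m x 1).
#' @param standard_errors m x k matrix of their standard errors.
#' @return a `pooled_coefficients` with per-coefficient `q_bar`, `w_bar`,
#'   `b`, `t_total`, `se` (= sqrt of `t_total`), `df`, `p_value`.
#' @export
pool_rubin <- function(estimates, standard_errors) {
  estimates <- as.matrix(estimates)
  standard_errors <- as.matrix(standard_errors)
  stopifnot(all(dim(estimates) == dim(standard_errors)))
  m <- nrow(estimates)
  if (m < 2) {
    warning("pool_rubin with m = 1: between-imputation variance set to 0")
  }
  q_bar <- colMeans(estimates)
  w_bar <- colMeans(standard_errors^2)
  b <- if (m > 1) apply(estimates, 2, stats::var) else rep(0, ncol(estimates))
  t_total <- w_bar + (1 + 1 / m) * b
  df <- ifelse(b > 0, (m - 1) * (1 + w_bar / ((1 + 1 / m) * b))^2, Inf)
  tstat <- q_bar / sqrt(t_total)
  p <- ifelse(is.finite(df), 2 * stats::pt(-abs(tstat), df),
              2 * stats::pnorm(-abs(tstat)))
  structure(list(q_bar = q_bar, w_bar = w_bar, b = b, t_total = t_total,
                 se = sqrt(t_total), df = df, p_value = p, m = m),
            class = "pooled_coefficients")
}

#' @export
as.data.frame.pooled_coefficients <- function(x, ...) {
  data.frame(term = names(x$q_bar) %||% seq_along(x$q_bar),
             estimate = unname(x$q_bar), se = unname(x$se),
             df = unname(x$df), p_value = unname(x$p_value),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pooled_coefficients <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}
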