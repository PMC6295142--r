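#' Enumerate the missingness patterns of a family table
#'
#' One pattern per distinct mask over the six relative columns (the child is
#' the response and must be fully observed, so at most 2^6 = 64 patterns are
#' possible). Each pattern's training pool is every row whose mask is
#' complete on at least that pattern's observed roles — a superset of the
#' rows exhibiting the pattern exactly, so richer rows contribute to
#' sparser patterns' fits.
#'
#' @param table a `family_table` with a fully observed child column.
#' @return list of `missingness_pattern`s: `observed_roles`, `row_ids`,
#'   `pool_ids`, `training_pool_size`, `key`.
#' @export
enumerate_patterns <- function(table) {
  stopifnot(inherits(table, "family_table"))
  if (!all(table$mask[, "child"])) {
    stop("enumerate_patterns requires a fully observed child column")
  }
  rel_mask <- table$mask[, RELATIVE_ROLES, drop = FALSE]
  keys <- apply(rel_mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  patterns <- lapply(unique(keys), function(k) {
    rows <- which(keys == k)
    obs <- RELATIVE_ROLES[rel_mask[rows[1], ]]
    pool <- which(apply(rel_mask[, obs, drop = FALSE], 1L, all))
    if (length(obs) == 0L) pool <- seq_len(nrow(rel_mask))
    structure(list(observed_roles = obs, row_ids = rows, pool_ids = pool,
                   training_pool_size = length(pool), key = k),
              class = "missingness_pattern")
  })
  patterns
}

#' Pattern-stratified "reduction method" fit and score
#'
#' The no-imputation gold standard: for every missingness pattern, restrict
#' the pattern's training pool to its observed covariates, split it at
#' random into training (`split_fraction`, floored, at least one test row)
#' and test parts, fit the chosen model on the training part and score mse
#' on the test part. Patterns whose pool is smaller than `min_train`
#' (default: covariate count + 3) are skipped and reported. The fitted
#' models are retained so new rows can be routed to their pattern's model.
#'
#' @param table a masked `family_table` (child fully observed).
#' @param model_tag `"linear"` or `"nn"`.
#' @param split_fraction training fraction in (0, 1), default 0.8.
#' @param min_train minimum training rows per pattern; default
#'   `length(observed_roles) + 3`.
#' @param seed master seed; each pattern splits on its own substream.
#' @param nn_args extra arguments for the neural-network fitter.
#' @return a `reduction_report`: `per_pattern_mse`, `mse_mean`, `mse_sd`,
#'   `model_tag`, `patterns` (with fitted models), `skipped` keys, and a
#'   `table` data.frame (pattern key, pool/train/test sizes, mse).
#' @export
reduction_fit <- function(table, model_tag = "linear", split_fraction = 0.8,
                          min_train = NULL, seed = 1, nn_args = list()) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  patterns <- enumerate_patterns(table)
  vals <- table$values
  fitted <- list()
  skipped <- character(0)
  rows <- list()
  for (pi in seq_along(patterns)) {
    pat <- patterns[[pi]]
    pool <- pat$pool_ids
    ncov <- length(pat$observed_roles)
    mt <- if (is.null(min_train)) ncov + 3L else min_train
    n_pool <- length(pool)
    n_train <- floor(split_fraction * n_pool)
    if (n_train >= n_pool) n_train <- n_pool - 1L
    if (n_train < mt) {
      skipped <- c(skipped, pat$key)
      next
    }
    set.seed(derive_seed(seed, 303L, pi))
    perm <- sample(pool)
    train <- perm[seq_len(n_train)]
    test <- perm[(n_train + 1L):n_pool]
    X_train <- vals[train, pat$observed_roles, drop = FALSE]
    X_test <- vals[test, pat$observed_roles, drop = FALSE]
    y_train <- vals[train, "child"]
    y_test <- vals[test, "child"]
    model <- tryCatch({
      if (model_tag == "linear" && ncov > 0) {
        linear_fit(X_train, y_train)
      } else if (model_tag == "nn" && ncov > 0) {
        do.call(nn_train, c(list(X = X_train, y = y_train), nn_args))
      } else {
        structure(list(mean = mean(y_train)), class = "mean_fit")
      }
    }, error = function(e) NULL)
    if (is.null(model)) {
      skipped <- c(skipped, pat$key)
      next
    }
    pred <- if (inherits(model, "mean_fit")) {
      rep(model$mean, length(y_test))
    } else {
      predict(model, X_test)
    }
    mse <- mean((pred - y_test)^2)
    fitted[[pat$key]] <- list(pattern = pat, model = model, mse = mse,
                              n_train = n_train, n_test = length(test))
    rows[[length(rows) + 1L]] <- data.frame(
      pattern = pattern_label(pat), pool = n_pool, train = n_train,
      test = length(test), mse = mse)
  }
  if (length(fitted) == 0L) stop("no pattern had a large enough training pool to fit")
  if (length(skipped) > 0) {
    warning(length(skipped), " pattern(s) skipped: training pool below minimum")
  }
  per_mse <- vapply(fitted, function(f) f$mse, numeric(1))
  structure(list(per_pattern_mse = per_mse,
                 mse_mean = mean(per_mse),
                 mse_sd = if (length(per_mse) > 1) stats::sd(per_mse) else 0,
                 model_tag = model_tag, fitted = fitted, skipped = skipped,
                 table = do.call(rbind, rows)),
            class = "reduction_report")
}

pattern_label <- function(pat) {
  shown <- c("child", ifelse(RELATIVE_ROLES %in% pat$observed_roles,
                             RELATIVE_ROLES, "-"))
  paste(shown, collapse = ",")
}

#' Route a new family row to its missingness pattern's model
#'
#' The row's observed-relative set must exactly match a fitted pattern;
#' otherwise an error names the nearest coarser fitted pattern (largest
#' observed set contained in the row's) rather than silently falling back.
#'
#' @param report a `reduction_report` from [reduction_fit()].
#' @param new_row named length-7 numeric vector (role order), `NA` where a
#'   relative is unobserved.
#' @return predicted child BMI (scalar).
#' @export
reduction_predict <- function(report, new_row) {
  stopifnot(length(new_row) == 7)
  names(new_row) <- FAMILY_ROLES
  obs <- RELATIVE_ROLES[!is.na(new_row[RELATIVE_ROLES])]
  key <- paste(as.integer(RELATIVE_ROLES %in% obs), collapse = "")
  entry <- report$fitted[[key]]
  if (is.null(entry)) {
    coarser <- Filter(function(f) all(f$pattern$observed_roles %in% obs),
                      report$fitted)
    hint <- if (length(coarser) > 0) {
      best <- which.max(vapply(coarser, function(f)
        length(f$pattern$observed_roles), numeric(1)))
      paste0("; nearest coarser fitted pattern: ",
             pattern_label(coarser[[best]]$pattern))
    } else ""
    stop("no model fitted for this row's missingness pattern", hint)
  }
  model <- entry$model
  if (inherits(model, "mean_fit")) return(model$mean)
  X <- matrix(new_row[entry$pattern$observed_roles], nrow = 1,
              dimnames = list(NULL, entry$pattern$observed_roles))
  drop(predict(model, X))
}

#' Write a reduction report as CSV
#'
#' One row per fitted pattern: mask string (observed roles spelled out,
#' `-` for missing), pool/train/test sizes and test mse.
#'
#' @param report a `reduction_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reduction_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
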