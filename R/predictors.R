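#' Ordinary least-squares fit of child BMI on relatives' BMI
#'
#' @param X n x p covariate matrix (the six relatives in the standard
#'   pipeline, but any p works).
#' @param y response vector (child BMI).
#' @return a `linear_fit` with `coefficients` (intercept first),
#'   `standard_errors`, `residual_variance` and `n_used`.
#' @export
linear_fit <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  k <- p + 1L
  if (n <= k) stop("linear_fit needs n > ", k, " rows, have ", n)
  D <- cbind(`(intercept)` = 1, X)
  qr_x <- qr(D)
  if (qr_x$rank < k) {
    bad <- colnames(D)[qr_x$pivot[(qr_x$rank + 1):k]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qr_x, y)
  rss <- sum(qr.resid(qr_x, y)^2)
  s2 <- rss / (n - k)
  se <- sqrt(s2 * diag(chol2inv(qr.R(qr_x))))
  names(se) <- names(coef)
  structure(list(coefficients = coef, standard_errors = se,
                 residual_variance = s2, n_used = n,
                 covariates = colnames(X)),
            class = "linear_fit")
}

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(cbind(1, newdata) %*% object$coefficients)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Build the list of (p_in + 1) x p_out weight matrices (bias in last row)
# for the given layer sizes, drawn uniform(-0.5, 0.5) from the session RNG.
init_nn_weights <- function(n_inputs, architecture) {
  sizes <- c(n_inputs, architecture, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    matrix(stats::runif((sizes[l] + 1L) * sizes[l + 1L], -0.5, 0.5),
           nrow = sizes[l] + 1L, ncol = sizes[l + 1L])
  })
}

#' Train a sigmoidal feed-forward network by full-batch backpropagation
#'
#' All units — hidden layers and the single output — are logistic sigmoids.
#' Inputs are z-scored on the training data and the response is mapped
#' affinely onto `[0.1, 0.9]` (inverted at prediction), so the sigmoidal
#' output can reach every training value without saturating. Weights start
#' uniform(-0.5, 0.5) from the session RNG (seed upstream for determinism)
#' and are updated by gradient descent on the summed squared error with a
#' bold-driver adaptive step from the base `learning_rate`. Training stops
#' when the gradient norm falls below `tol` or after `max_epochs`.
#'
#' @param X n x p covariate matrix.
#' @param y response vector.
#' @param architecture hidden-layer sizes, default `c(2, 1)`.
#' @param learning_rate base step size (default 0.01).
#' @param tol gradient-norm stopping threshold (default 1e-4).
#' @param max_epochs epoch cap (default 600; the cap doubles as mild
#'   regularization against leave-one-out overfitting).
#' @return a `neural_net` with the layer weights and scaling constants.
#' @export
nn_train <- function(X, y, architecture = c(2, 1), learning_rate = 0.01,
                     tol = 1e-4, max_epochs = 600) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("nn_train needs at least 2 rows")
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[!is.finite(x_scale) | x_scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, x_center, `-`), 2, x_scale, `/`)
  y_min <- min(y)
  y_max <- max(y)
  ys <- if (y_max > y_min) 0.1 + 0.8 * (y - y_min) / (y_max - y_min) else rep(0.5, n)
  W0 <- init_nn_weights(ncol(X), architecture)
  fit <- nn_gd_train(Xs, ys, W0, learning_rate, tol, as.integer(max_epochs))
  if (isTRUE(fit$diverged)) {
    stop("neural-network training diverged; try a smaller learning_rate")
  }
  structure(list(architecture = as.integer(architecture),
                 weights = fit$weights,
                 x_center = x_center, x_scale = x_scale,
                 y_min = y_min, y_max = y_max,
                 epochs = fit$epochs, grad_norm = fit$grad_norm,
                 train_error = fit$error,
                 covariates = colnames(X)),
            class = "neural_net")
}

#' Forward pass of a trained network
#'
#' Standardizes the inputs with the stored training constants, propagates
#' through the sigmoid layers, and inverts the response scaling. A network
#' trained on a constant response predicts that constant.
#'
#' @param net a `neural_net`.
#' @param X_new matrix of new covariate rows (same column count as training).
#' @return numeric vector of predicted child BMI.
#' @export
nn_predict <- function(net, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(net$x_center)) {
    stop("X_new must have ", length(net$x_center), " columns")
  }
  A <- sweep(sweep(X_new, 2, net$x_center, `-`), 2, net$x_scale, `/`)
  for (W in net$weights) {
    p <- nrow(W) - 1L
    Z <- A %*% W[seq_len(p), , drop = FALSE]
    Z <- sweep(Z, 2, W[p + 1L, ], `+`)
    A <- sigmoid(Z)
  }
  o <- drop(A)
  if (net$y_max > net$y_min) {
    net$y_min + (o - 0.1) / 0.8 * (net$y_max - net$y_min)
  } else {
    rep(net$y_min, length(o))
  }
}

#' @export
predict.neural_net <- function(object, newdata, ...) nn_predict(object, newdata)

#' Save a trained network as plain text
#'
#' Key-value header (architecture, scaling constants) followed by one
#' whitespace-separated block per layer weight matrix, so cross-validation
#' runs can be audited without binary artefacts.
#'
#' @param net a `neural_net`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nn <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) paste(trimws(formatC(x, format = "g", digits = 17)),
                           collapse = " ")
  writeLines(c(
    paste0("architecture: ", paste(net$architecture, collapse = " ")),
    paste0("x_center: ", fmt(net$x_center)),
    paste0("x_scale: ", fmt(net$x_scale)),
    paste0("y_min: ", fmt(net$y_min)),
    paste0("y_max: ", fmt(net$y_max)),
    paste0("n_layers: ", length(net$weights))
  ), con)
  for (W in net$weights) {
    writeLines(paste0("layer: ", nrow(W), " ", ncol(W)), con)
    for (i in seq_len(nrow(W))) writeLines(fmt(W[i, ]), con)
  }
  invisible(path)
}

#' Load a network saved by [write_nn()]
#'
#' @param path file written by [write_nn()].
#' @return a `neural_net`.
#' @export
read_nn <- function(path) {
  lines <- readLines(path)
  val <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub(paste0("^", key, ": "), "", ln)), " +")[[1]])
  }
  n_layers <- as.integer(val("n_layers"))
  weights <- vector("list", n_layers)
  idx <- grep("^layer: ", lines)
  for (l in seq_len(n_layers)) {
    dims <- as.integer(strsplit(sub("^layer: ", "", lines[idx[l]]), " ")[[1]])
    rows <- lines[(idx[l] + 1):(idx[l] + dims[1])]
    weights[[l]] <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), " +")[[1]])
    }))
  }
  structure(list(architecture = as.integer(val("architecture")),
                 weights = weights,
                 x_center = val("x_center"), x_scale = val("x_scale"),
                 y_min = val("y_min"), y_max = val("y_max")),
            class = "neural_net")
}

#' Additive model fitted by backfitting cubic smoothing splines
#'
#' A nonlinearity diagnostic: the response is modelled as an intercept plus a
#' sum of univariate smooth functions of the covariates, with no automatic
#' interactions. Components start at zero and are updated in turn by a cubic
#' smoothing spline (fixed effective degrees of freedom) fitted to the
#' partial residuals, each component re-centred to mean zero over the
#' training data, until the largest component change falls below `tol`.
#'
#' @param X n x p covariate matrix.
#' @param y response vector.
#' @param target_df effective degrees of freedom per component (default 4).
#' @param tol convergence threshold on the maximal component change
#'   (default 1e-6 on the root-mean-square scale).
#' @param max_cycles backfitting cycle cap (default 50).
#' @return an `additive_fit` with the per-covariate spline smooths, their
#'   centring constants, effective df and the intercept.
#' @export
additive_backfit <- function(X, y, target_df = 4, tol = 1e-6, max_cycles = 50) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p * target_df) {
    stop("additive_backfit needs n > p * target_df (", p * target_df, ")")
  }
  alpha <- mean(y)
  comps <- matrix(0, n, p)
  smooths <- vector("list", p)
  centers <- numeric(p)
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    max_change <- 0
    for (j in seq_len(p)) {
      partial <- y - alpha - rowSums(comps[, -j, drop = FALSE])
      ss <- stats::smooth.spline(X[, j], partial, df = target_df)
      fj <- stats::predict(ss, X[, j])$y
      centers[j] <- mean(fj)
      fj <- fj - centers[j]
      max_change <- max(max_change, sqrt(mean((fj - comps[, j])^2)))
      comps[, j] <- fj
      smooths[[j]] <- ss
    }
    if (max_change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("backfitting did not converge in ", max_cycles, " cycles")
  }
  structure(list(intercept = alpha, smooths = smooths, centers = centers,
                 fitted = alpha + rowSums(comps),
                 effective_df = vapply(smooths, function(s) s$df, numeric(1)),
                 covariates = colnames(X), converged = converged),
            class = "additive_fit")
}

#' @export
predict.additive_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- rep(object$intercept, nrow(newdata))
  for (j in seq_along(object$smooths)) {
    out <- out + stats::predict(object$smooths[[j]], newdata[, j])$y -
      object$centers[j]
  }
  out
}
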