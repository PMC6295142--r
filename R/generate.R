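#' Default correlation matrix among the six relatives
#'
#' Exchangeable-by-relationship structure: spouses within a grandparental
#' couple 0.25, parent vs. own parents 0.30, mother vs. father 0.20, in-law
#' pairs 0.05, across-side grandparents 0.02. Verified positive definite.
#'
#' @return a 6 x 6 correlation matrix (mother, father, mgm, mgf, pgm, pgf).
#' @export
default_relative_corr <- function() {
  r <- diag(6)
  rownames(r) <- colnames(r) <- RELATIVE_ROLES
  set_pair <- function(a, b, v) {
    r[a, b] <<- v
    r[b, a] <<- v
  }
  set_pair("mother", "father", 0.20)
  set_pair("mother", "mgm", 0.30); set_pair("mother", "mgf", 0.30)
  set_pair("father", "pgm", 0.30); set_pair("father", "pgf", 0.30)
  set_pair("mother", "pgm", 0.05); set_pair("mother", "pgf", 0.05)
  set_pair("father", "mgm", 0.05); set_pair("father", "mgf", 0.05)
  set_pair("mgm", "mgf", 0.25); set_pair("pgm", "pgf", 0.25)
  set_pair("mgm", "pgm", 0.02); set_pair("mgm", "pgf", 0.02)
  set_pair("mgf", "pgm", 0.02); set_pair("mgf", "pgf", 0.02)
  r
}

#' Configuration of the synthetic family-BMI generator
#'
#' The generator emulates a three-generation cohort: 567 families by default,
#' relatives' BMI drawn from a multivariate Gaussian, and the child's BMI
#' built from configurable linear, smooth-nonlinear and pairwise-interaction
#' effects of the relatives plus Gaussian noise. Nonlinear and interaction
#' terms act on internally standardized relatives, so their amplitudes are in
#' child-BMI units per standard deviation of the relative. Default missing
#' rates are the cohort's per-role missing-data fractions (child fully
#' observed).
#'
#' Defaults are calibrated so that Var(child BMI) is about 3.0 kg^2/m^4, the
#' total response variance implied jointly by the published mse/R-squared
#' pairs for this cohort (see the reference table shipped with the package).
#'
#' @param seed integer seed; mandatory, every draw is a deterministic
#'   function of it.
#' @param n_families number of families (default 567).
#' @param relative_means,relative_sds length-6 numeric vectors of BMI means
#'   and standard deviations for mother, father, mgm, mgf, pgm, pgf.
#' @param relative_corr 6 x 6 correlation matrix among the relatives.
#' @param linear_effects length-6 slopes (child-BMI units per relative-BMI
#'   unit).
#' @param nonlinear_effects list of `list(role=, fun=, amplitude=)` entries;
#'   `fun` is `"quadratic"` (amplitude * (z^2 - 1)) or `"sine"`
#'   (amplitude * sin(pi z / 2)) of the standardized relative z.
#' @param interaction_effects list of `list(roles = c(role1, role2),
#'   coefficient=)` entries acting on products of standardized relatives.
#' @param intercept child-BMI intercept (default gives mean child BMI near
#'   15.5, typical at age 5).
#' @param noise_sd residual standard deviation of child BMI (default 1.27,
#'   which together with the default effects gives Var(child) near 3.0).
#' @param missing_rates length-7 per-role MCAR missingness probabilities in
#'   role order (child first; default child = 0).
#' @param couple_block_prob probability that a grandparental couple shares a
#'   single missingness draw (default 0, independent cells).
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed,
                             n_families = 567,
                             relative_means = c(25.5, 27.5, 27.0, 27.5, 27.0, 27.5),
                             relative_sds = c(4.5, 4.0, 4.5, 4.0, 4.5, 4.0),
                             relative_corr = default_relative_corr(),
                             linear_effects = c(0.10, 0.08, 0.06, 0.04, 0.02, 0.02),
                             nonlinear_effects = list(
                               list(role = "father", fun = "quadratic", amplitude = 0.25),
                               list(role = "mgm", fun = "sine", amplitude = 0.50),
                               list(role = "pgf", fun = "quadratic", amplitude = 0.20)
                             ),
                             interaction_effects = list(
                               list(roles = c("mother", "father"), coefficient = 0.30)
                             ),
                             intercept = 6.88,
                             noise_sd = 1.27,
                             missing_rates = c(0.0, 0.012, 0.579, 0.561, 0.716, 0.679, 0.774),
                             couple_block_prob = 0.0) {
  if (missing(seed)) stop("generator_config: 'seed' is mandatory")
  cfg <- list(
    seed = as.integer(seed), n_families = as.integer(n_families),
    relative_means = as.numeric(relative_means),
    relative_sds = as.numeric(relative_sds),
    relative_corr = as.matrix(relative_corr),
    linear_effects = as.numeric(linear_effects),
    nonlinear_effects = nonlinear_effects,
    interaction_effects = interaction_effects,
    intercept = intercept, noise_sd = noise_sd,
    missing_rates = as.numeric(missing_rates),
    couple_block_prob = couple_block_prob
  )
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_families >= 0)
  if (length(cfg$relative_means) != 6 || length(cfg$relative_sds) != 6 ||
      length(cfg$linear_effects) != 6) {
    stop("relative_means, relative_sds and linear_effects must have length 6")
  }
  if (any(cfg$relative_sds <= 0)) stop("all relative_sds must be > 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  r <- cfg$relative_corr
  if (!all(dim(r) == c(6, 6))) stop("relative_corr must be 6 x 6")
  if (max(abs(r - t(r))) > 1e-8) stop("relative_corr must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("relative_corr must have unit diagonal")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("relative_corr is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  if (length(cfg$missing_rates) != 7) stop("missing_rates must have length 7")
  if (any(cfg$missing_rates < 0 | cfg$missing_rates > 1)) {
    stop("missing_rates must lie in [0, 1]")
  }
  if (cfg$couple_block_prob < 0 || cfg$couple_block_prob > 1) {
    stop("couple_block_prob must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Read a generator configuration from a YAML key-value file
#'
#' All `generator_config()` fields are addressable; `seed` is required.
#' `relative_corr` may be given as a list of 6 rows.
#'
#' @param path YAML file path.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("generator config file must set 'seed'")
  if (!is.null(raw$relative_corr)) {
    raw$relative_corr <- do.call(rbind, raw$relative_corr)
  }
  do.call(generator_config, raw)
}

smooth_term <- function(fun, z, amplitude) {
  switch(fun,
    quadratic = amplitude * (z^2 - 1),
    sine = amplitude * sin(pi * z / 2),
    stop("unknown smooth-function tag: ", fun)
  )
}

#' Simulate complete family BMI tables
#'
#' Relatives are drawn from the multivariate Gaussian implied by
#' `relative_means`, `relative_sds` and `relative_corr`; the child column is
#' the configured intercept plus linear, smooth-nonlinear and interaction
#' effects of the relatives plus `N(0, noise_sd^2)` noise. Deterministic
#' given `config$seed`.
#'
#' @param config a `generator_config`.
#' @return a complete `family_table` (all cells observed).
#' @export
generate_families <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_families
  U <- tryCatch(chol(config$relative_corr),
                error = function(e) stop("relative_corr is not positive definite: ",
                                         conditionMessage(e)))
  set.seed(config$seed)
  Z <- matrix(stats::rnorm(n * 6), nrow = n, ncol = 6)
  Zc <- Z %*% U # correlated standard-normal relatives
  X <- sweep(sweep(Zc, 2, config$relative_sds, `*`), 2, config$relative_means, `+`)
  colnames(X) <- RELATIVE_ROLES
  colnames(Zc) <- RELATIVE_ROLES

  child <- rep(config$intercept, n)
  if (n > 0) {
    child <- child + drop(X %*% config$linear_effects)
    for (nl in config$nonlinear_effects) {
      child <- child + smooth_term(nl$fun, Zc[, nl$role], nl$amplitude)
    }
    for (ia in config$interaction_effects) {
      child <- child + ia$coefficient * Zc[, ia$roles[1]] * Zc[, ia$roles[2]]
    }
    child <- child + stats::rnorm(n, 0, config$noise_sd)
  }
  family_table(cbind(child = child, X))
}

#' Mask cells of a complete table, missing completely at random
#'
#' Each cell is masked independently with its role's probability. With
#' probability `couple_block_prob` a grandparental couple (mgm+mgf or
#' pgm+pgf) instead shares one Bernoulli draw at the mean of the couple's two
#' rates, so both members are masked or neither is. The pre-masking values
#' are kept on the returned table's `truth` sheet for scoring only.
#'
#' @param table a complete `family_table`.
#' @param missing_rates length-7 per-role masking probabilities.
#' @param couple_block_prob probability of a joint couple draw.
#' @param seed integer seed.
#' @return a masked `family_table` with `truth` attached.
#' @export
apply_mcar <- function(table, missing_rates, couple_block_prob = 0, seed) {
  stopifnot(inherits(table, "family_table"))
  if (!is_complete(table)) stop("apply_mcar expects a fully observed table")
  if (length(missing_rates) != 7 || any(missing_rates < 0 | missing_rates > 1)) {
    stop("missing_rates must be 7 probabilities in [0, 1]")
  }
  if (couple_block_prob < 0 || couple_block_prob > 1) {
    stop("couple_block_prob must lie in [0, 1]")
  }
  n <- n_families(table)
  set.seed(seed)
  miss <- matrix(stats::runif(n * 7), n, 7) < rep(missing_rates, each = n)
  if (couple_block_prob > 0 && n > 0) {
    for (couple in list(c("mgm", "mgf"), c("pgm", "pgf"))) {
      j <- match(couple, FAMILY_ROLES)
      joint <- stats::runif(n) < couple_block_prob
      shared <- stats::runif(n) < mean(missing_rates[j])
      miss[joint, j[1]] <- shared[joint]
      miss[joint, j[2]] <- shared[joint]
    }
  }
  vals <- table$values
  vals[miss] <- NA_real_
  family_table(vals, mask = !miss, truth = table$values)
}

#' Simulate a masked family table in one call
#'
#' [generate_families()] followed by [apply_mcar()] with the rates and block
#' probability of the same configuration; masking uses a substream seed
#' derived from `config$seed`.
#'
#' @param config a `generator_config`.
#' @return a masked `family_table` with `truth` attached.
#' @export
simulate_family_data <- function(config) {
  complete <- generate_families(config)
  apply_mcar(complete, config$missing_rates, config$couple_block_prob,
             seed = derive_seed(config$seed, 7L))
}
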