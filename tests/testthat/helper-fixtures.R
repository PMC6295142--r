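# Small fixtures shared across test files; everything is built in code.

# A generator configuration scaled down for fast tests.
tiny_config <- function(seed = 1, n = 60, ...) {
  generator_config(seed = seed, n_families = n, ...)
}

# A generator with purely linear child model (no smooth or interaction terms).
linear_config <- function(seed = 1, n = 500, noise_sd = 1.0, ...) {
  generator_config(seed = seed, n_families = n,
                   nonlinear_effects = list(),
                   interaction_effects = list(),
                   noise_sd = noise_sd, ...)
}

# Build a family_table directly from a values matrix (NA = missing).
make_table <- function(values) family_table(as.matrix(values))

# A small complete table with known structure.
complete_toy_table <- function(seed = 42, n = 30) {
  cfg <- tiny_config(seed = seed, n = n, missing_rates = rep(0, 7))
  generate_families(cfg)
}

# Independent least-squares oracle: plain normal equations.
normal_equations <- function(X, y) {
  D <- cbind(1, as.matrix(X))
  drop(solve(crossprod(D), crossprod(D, y)))
}
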