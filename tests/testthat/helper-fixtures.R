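# Shared fixtures and oracles for the test suite.  Expensive benchmark runs
# used by several acceptance checks are computed once per session and cached.

.volnorm_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .volnorm_test_cache, inherits = FALSE)) {
    assign(key, compute(), envir = .volnorm_test_cache)
  }
  get(key, envir = .volnorm_test_cache, inherits = FALSE)
}

# Central-difference Jacobian used as the derivative oracle.
numeric_jacobian <- function(fn, par, h = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (k in seq_along(par)) {
    e <- rep(0, length(par))
    e[k] <- h
    J[, k] <- (fn(par + e) - fn(par - e)) / (2 * h)
  }
  J
}

quiet_fit <- function(...) suppressWarnings(fit_volumes(...))

# Small mass table with exactly proportional rows: M = C * V with constant C,
# so PQN recovers V / median(V) exactly.
constant_concentration_data <- function(v = c(1, 2, 4), conc = c(3, 5, 7, 11)) {
  m <- outer(v, conc)
  colnames(m) <- paste0("m", seq_along(conc))
  tibble::tibble(time = seq_along(v) - 1, !!!as.data.frame(m))
}

# v1 benchmark cell shared by several acceptance checks:
# n_metabolites = 60, 20 time points, 20 % CV error.
# PQN / PKM_minimal / MIX_minimal on 100 replicates.
acceptance_minimal_cell <- function() {
  cache_get("minimal_cell", function() {
    grid <- benchmark_grid(
      versions = "v1", n_metabolites = 60, noise_fractions = 0,
      models = c("pqn", "pkm_minimal", "mix_minimal"), replicates = 100
    )
    run_benchmark(grid, seed = 20220916, n_timepoints = 20, cv = 0.2,
                  n_starts = 25)
  })
}

# The same cell's PKM_full fits on 20 replicates (the expensive model).
acceptance_full_cell <- function() {
  cache_get("full_cell", function() {
    grid <- benchmark_grid(
      versions = "v1", n_metabolites = 60, noise_fractions = 0,
      models = "pkm_full", replicates = 20
    )
    run_benchmark(grid, seed = 20220916, n_timepoints = 20, cv = 0.2,
                  n_starts = 25)
  })
}
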