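#' Toy-model kinetic parameters
#'
#' Kinetic parameters of the four-metabolite toy model that seeds every
#' synthetic data set: a caffeine-like parent compound and three slower
#' degradation-product analogues (paraxanthine-, theobromine-, and
#' theophylline-like).  All four have `lag = 0` (absorption starts at time
#' zero), mirroring a single-dose caffeine experiment after dietary
#' abstinence; caffeine and paraxanthine have no baseline (`d = 0`), while
#' theobromine and theophylline carry a small dietary baseline
#' concentration (`d > 0`), which also anchors the measured masses at the
#' first time point so that the volume there stays identifiable for purely
#' kinetic fits.  All values lie inside the fitting bounds
#' \eqn{(0,0,0,0,0) \le (k_a,k_e,c_0,lag,d) \le (3,3,5,15,3)}.
#'
#' @return A tibble with columns `metabolite`, `k_a`, `k_e`, `c0`, `lag`, `d`.
#' @examples
#' toy_kinetics()
#' @export
toy_kinetics <- function() {
  tibble::tibble(
    metabolite = c("caffeine", "paraxanthine", "theobromine", "theophylline"),
    k_a = c(1.2, 0.9, 0.5, 0.7),
    k_e = c(0.5, 0.35, 0.18, 0.12),
    c0 = c(4, 2.5, 1.0, 0.6),
    lag = c(0, 0, 0, 0),
    d = c(0, 0, 0.3, 0.05)
  )
}

#' Default equidistant sampling grid
#'
#' @param n_timepoints Number of samples.
#' @param t_max End of the sampling window (h).
#' @return Numeric vector of `n_timepoints` equidistant times on
#'   `[0, t_max]`.
#' @export
default_time_grid <- function(n_timepoints = 20, t_max = 15) {
  seq(0, t_max, length.out = n_timepoints)
}

#' Toy-model concentration time series
#'
#' Evaluates the four [toy_kinetics()] Bateman curves on a time grid; this
#' is the targeted (known-kinetics) block of every synthetic data set.
#'
#' @param t Time grid (h); defaults to 20 equidistant points on 0--15 h.
#' @return A tibble with a `time` column and one concentration column per
#'   toy metabolite.
#' @examples
#' toy_base_concentrations()
#' @export
toy_base_concentrations <- function(t = default_time_grid()) {
  tk <- toy_kinetics()
  cols <- lapply(seq_len(nrow(tk)), function(i) {
    bateman(t, tk$k_a[i], tk$k_e[i], tk$c0[i], tk$lag[i], tk$d[i])
  })
  names(cols) <- tk$metabolite
  tibble::tibble(time = t, !!!cols)
}

#' Parameter table for fitting synthetic data
#'
#' Builds the [kinetic_parameter_table()] used throughout the benchmark:
#' the first four (toy) metabolites have `c0`, `lag`, and `d` fixed at
#' their known values (known dose, known absorption start, not
#' endogenously produced) while their `k_a`, `k_e` stay free in
#' \eqn{[0,3]}; all parameters of any further metabolites are free within
#' the default bounds.
#'
#' @param metabolites Metabolite names; the first four are matched to the
#'   toy model in order.
#' @return A parameter table tibble.
#' @export
toy_parameter_table <- function(metabolites) {
  tk <- toy_kinetics()
  n_toy <- min(4L, length(metabolites))
  fixed <- lapply(seq_len(n_toy), function(i) {
    c(c0 = tk$c0[i], lag = tk$lag[i], d = tk$d[i])
  })
  names(fixed) <- metabolites[seq_len(n_toy)]
  kinetic_parameter_table(metabolites, fixed = fixed)
}

#' Sample volumes from a truncated log-normal distribution
#'
#' Draws i.i.d. sample volumes from a log-normal distribution truncated by
#' rejection to `[lower, upper]`.  Defaults emulate finger-sweat volumes:
#' untruncated median 0.3 uL, geometric standard deviation 2.5, truncated
#' to 0.05--4 uL.
#'
#' @param n Number of draws.
#' @param meanlog,sdlog Log-space parameters of the untruncated
#'   distribution.
#' @param lower,upper Truncation bounds (uL).
#' @param seed Optional integer seed (the caller's RNG state is restored).
#'
#' @return Numeric vector of `n` volumes, all within `[lower, upper]`.
#' @examples
#' sample_volumes(5, seed = 1)
#' @export
sample_volumes <- function(n, meanlog = log(0.3), sdlog = log(2.5),
                           lower = 0.05, upper = 4, seed = NULL) {
  if (n < 1) abort("`n` must be >= 1.")
  draw <- function() {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rlnorm(2L * (n - length(out)) + 10L, meanlog, sdlog)
      out <- c(out, x[x >= lower & x <= upper])
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) return(draw())
  with_preserved_rng({
    set.seed(seed)
    draw()
  })
}

# Multiplicative measurement error: Normal(1, cv), truncated below at 0.01
# to preserve positivity.
sample_epsilon <- function(n_timepoints, n_metabolites, cv = 0.2) {
  e <- matrix(rnorm(n_timepoints * n_metabolites, mean = 1, sd = cv),
              nrow = n_timepoints)
  pmax(e, 0.01)
}

# Assemble a synthetic dataset from its ground-truth components.
# Volume-affected columns: M_j = C_j * V * eps; noise columns: M_j = C_j * eps.
build_dataset <- function(t, C, V, epsilon, noise_mask, version, seed,
                          kinetics = NULL, n_targeted = 4L) {
  M <- C * epsilon
  if (any(!noise_mask)) {
    M[, !noise_mask] <- M[, !noise_mask, drop = FALSE] * V
  }
  data <- tibble::tibble(time = t)
  data[colnames(C)] <- as.data.frame(M)
  structure(
    list(
      data = data, concentrations = C, volumes = V, epsilon = epsilon,
      noise_mask = noise_mask, version = version, seed = seed,
      kinetics = kinetics, n_targeted = n_targeted
    ),
    class = "volnorm_dataset"
  )
}

#' Simulate benchmark data sets
#'
#' Generators for the three synthetic-data strategies used to benchmark
#' the normalization models.  All three start from the four
#' [toy_base_concentrations()] metabolites, append
#' `n_metabolites - 4` untargeted concentration profiles, sample true
#' volumes from [sample_volumes()], apply multiplicative normal error with
#' coefficient of variation `cv`, and assemble measured masses as
#' \eqn{\tilde M_j(t_i) = C_j(t_i)\, V(t_i)\, \epsilon_{ij}}.
#'
#' * `simulate_v1()` ("sampled kinetics") appends modified Bateman curves
#'   with parameters drawn uniformly within
#'   \eqn{(0,0,0,0,0) \le (k_a,k_e,c_0,lag,d) \le (3,3,5,15,3)} -- every
#'   profile is kinetically describable.
#' * `simulate_v2()` ("sampled mean and standard deviation") appends
#'   profiles that are i.i.d. log-normal draws per time point, with each
#'   profile's mean and standard deviation themselves drawn from log-normal
#'   meta-distributions -- randomly behaving, not kinetically describable.
#' * `simulate_v3()` ("sampled from real data") appends a
#'   without-replacement sample of columns from a ground-truth
#'   concentration matrix (by default the packaged synthetic stand-in from
#'   [synthetic_ground_truth()]).
#'
#' @param n_metabolites Total number of metabolites (>= 4; the first four
#'   are the toy model).
#' @param n_timepoints Number of equidistant time points on 0--15 h.
#' @param cv Coefficient of variation of the multiplicative error (0.2
#'   emulates 20 % CV LC-MS error; 0 disables error).
#' @param seed Integer seed; the same seed reproduces the data set
#'   bit-identically.
#' @param meta For `simulate_v2()`: log-normal hyperparameters, a list
#'   with `mean_meanlog`, `mean_sdlog`, `sd_meanlog`, `sd_sdlog`.
#' @param ground_truth For `simulate_v3()`: data frame of ground-truth
#'   concentration profiles (`time` column + metabolite columns) with
#'   `n_timepoints` rows; `NULL` uses [synthetic_ground_truth()].
#' @param volume_args List of arguments forwarded to [sample_volumes()].
#'
#' @return A `volnorm_dataset`: a list with the measured-mass tibble
#'   `data`, ground-truth `concentrations`, `volumes`, `epsilon`,
#'   `noise_mask`, and (for v1) the true `kinetics`.
#' @examples
#' ds <- simulate_v1(n_metabolites = 10, seed = 1)
#' ds
#' @export
simulate_v1 <- function(n_metabolites = 60, n_timepoints = 20, cv = 0.2,
                        seed = 1, volume_args = list()) {
  check_n_metabolites(n_metabolites)
  t <- default_time_grid(n_timepoints)
  with_preserved_rng({
    set.seed(child_seed(seed, 1L))
    base <- toy_base_concentrations(t)
    n_new <- n_metabolites - 4L
    lowerb <- c(0, 0, 0, 0, 0)
    upperb <- c(3, 3, 5, 15, 3)
    kin <- toy_kinetics()
    C <- as.matrix(base[-1L])
    if (n_new > 0L) {
      pars <- matrix(runif(5L * n_new, lowerb, upperb), ncol = n_new)
      newC <- apply(pars, 2L, function(p) bateman_p(t, p))
      nm <- sprintf("met_%02d", 4L + seq_len(n_new))
      colnames(newC) <- nm
      C <- cbind(C, newC)
      kin <- dplyr::bind_rows(kin, tibble::tibble(
        metabolite = nm, k_a = pars[1L, ], k_e = pars[2L, ],
        c0 = pars[3L, ], lag = pars[4L, ], d = pars[5L, ]
      ))
    }
    V <- do.call(sample_volumes, c(list(n = n_timepoints), volume_args))
    eps <- sample_epsilon(n_timepoints, n_metabolites, cv)
    build_dataset(t, C, V, eps, rep(FALSE, n_metabolites), "v1", seed,
                  kinetics = kin)
  })
}

#' Default meta-distribution hyperparameters for simulation v2
#'
#' Log-normal hyperparameters for the populations of per-metabolite means
#' and standard deviations.  These are synthetic stand-ins chosen so that
#' profile means span roughly two orders of magnitude with per-profile
#' scatter comparable to the mean; they are configurable via the `meta`
#' argument of [simulate_v2()].
#'
#' @return A named list with `mean_meanlog`, `mean_sdlog`, `sd_meanlog`,
#'   `sd_sdlog`.
#' @export
v2_meta_defaults <- function() {
  list(
    mean_meanlog = log(0.5), mean_sdlog = 1.0,
    sd_meanlog = log(0.2), sd_sdlog = 1.0
  )
}

#' @rdname simulate_v1
#' @export
simulate_v2 <- function(n_metabolites = 60, n_timepoints = 20, cv = 0.2,
                        seed = 1, meta = v2_meta_defaults(),
                        volume_args = list()) {
  check_n_metabolites(n_metabolites)
  t <- default_time_grid(n_timepoints)
  with_preserved_rng({
    set.seed(child_seed(seed, 2L))
    base <- toy_base_concentrations(t)
    C <- as.matrix(base[-1L])
    n_new <- n_metabolites - 4L
    if (n_new > 0L) {
      m <- rlnorm(n_new, meta$mean_meanlog, meta$mean_sdlog)
      s <- rlnorm(n_new, meta$sd_meanlog, meta$sd_sdlog)
      # log-normal with target arithmetic mean m and sd s
      sdl <- sqrt(log1p((s / m)^2))
      mnl <- log(m) - sdl^2 / 2
      newC <- vapply(seq_len(n_new), function(j) {
        rlnorm(n_timepoints, mnl[j], sdl[j])
      }, numeric(n_timepoints))
      colnames(newC) <- sprintf("met_%02d", 4L + seq_len(n_new))
      C <- cbind(C, newC)
    }
    V <- do.call(sample_volumes, c(list(n = n_timepoints), volume_args))
    eps <- sample_epsilon(n_timepoints, n_metabolites, cv)
    build_dataset(t, C, V, eps, rep(FALSE, n_metabolites), "v2", seed)
  })
}

#' Synthetic ground-truth concentration matrix
#'
#' A synthetic stand-in for a PQN-normalized untargeted real data matrix
#' used as the sampling pool for [simulate_v3()]: a reproducible mixture
#' of kinetically describable (modified Bateman) and randomly behaving
#' (log-normal) concentration profiles.  Generated programmatically from a
#' fixed seed so the fixture ships as code, not data.
#'
#' @param n_metabolites Number of profiles.
#' @param n_timepoints Time points on the default 0--15 h grid.
#' @param bateman_fraction Fraction of profiles that follow Bateman
#'   kinetics (the remainder are log-normal noise profiles).
#' @param seed Seed of the fixture.
#' @return A tibble with a `time` column and one profile column per
#'   metabolite.
#' @export
synthetic_ground_truth <- function(n_metabolites = 100, n_timepoints = 20,
                                   bateman_fraction = 0.5, seed = 220916) {
  t <- default_time_grid(n_timepoints)
  with_preserved_rng({
    set.seed(child_seed(seed, 3L))
    n_bate <- round(bateman_fraction * n_metabolites)
    cols <- vector("list", n_metabolites)
    for (j in seq_len(n_metabolites)) {
      if (j <= n_bate) {
        p <- runif(5L, c(0, 0, 0, 0, 0), c(3, 3, 5, 15, 3))
        cols[[j]] <- pmax(bateman_p(t, p), 1e-4)
      } else {
        m <- rlnorm(1L, log(0.5), 1)
        s <- rlnorm(1L, log(0.2), 1)
        sdl <- sqrt(log1p((s / m)^2))
        cols[[j]] <- rlnorm(n_timepoints, log(m) - sdl^2 / 2, sdl)
      }
    }
    names(cols) <- sprintf("gt_%03d", seq_len(n_metabolites))
    tibble::tibble(time = t, !!!cols)
  })
}

#' @rdname simulate_v1
#' @export
simulate_v3 <- function(n_metabolites = 60, n_timepoints = 20, cv = 0.2,
                        seed = 1, ground_truth = NULL, volume_args = list()) {
  check_n_metabolites(n_metabolites)
  t <- default_time_grid(n_timepoints)
  gt <- ground_truth %||% synthetic_ground_truth(n_timepoints = n_timepoints)
  gt_m <- as.matrix(gt[setdiff(names(gt), "time")])
  if (nrow(gt_m) != n_timepoints) {
    abort("`ground_truth` must have `n_timepoints` rows.")
  }
  n_new <- n_metabolites - 4L
  if (n_new > ncol(gt_m)) {
    abort("Requested more metabolites than the ground-truth pool provides.")
  }
  with_preserved_rng({
    set.seed(child_seed(seed, 4L))
    base <- toy_base_concentrations(t)
    C <- as.matrix(base[-1L])
    if (n_new > 0L) {
      pick <- sample(ncol(gt_m), n_new)
      newC <- gt_m[, pick, drop = FALSE]
      C <- cbind(C, newC)
    }
    V <- do.call(sample_volumes, c(list(n = n_timepoints), volume_args))
    eps <- sample_epsilon(n_timepoints, n_metabolites, cv)
    build_dataset(t, C, V, eps, rep(FALSE, n_metabolites), "v3", seed)
  })
}

check_n_metabolites <- function(n) {
  if (n < 4L) abort("`n_metabolites` must be >= 4 (the first 4 are the toy model).")
}

#' Flag a fraction of untargeted metabolites as volume-independent noise
#'
#' Re-generates a synthetic data set with `round(f_n * n_metabolites)`
#' untargeted columns flagged as noise, i.e. contamination whose measured
#' mass is independent of the sample volume:
#' \eqn{\tilde M_{n,j}(t_i) = C_j(t_i)\,\epsilon_{ij}} (no volume factor).
#' Targeted (toy) metabolites are never flagged -- with known
#' pharmacokinetic behaviour one can be confident their signal is not
#' contamination -- so `f_n` may be at most
#' `(n_metabolites - 4) / n_metabolites`.
#'
#' @param ds A `volnorm_dataset`.
#' @param f_n Noise fraction in `[0, 0.95]`.
#' @return A `volnorm_dataset` with updated `noise_mask` and measured
#'   masses; `f_n = 0` returns the input unchanged.
#' @examples
#' ds <- simulate_v3(n_metabolites = 20, seed = 1)
#' noisy <- apply_noise_fraction(ds, 0.5)
#' sum(noisy$noise_mask)
#' @export
apply_noise_fraction <- function(ds, f_n) {
  if (!inherits(ds, "volnorm_dataset")) abort("`ds` must be a volnorm_dataset.")
  if (f_n < 0 || f_n > 0.95) abort("`f_n` must be in [0, 0.95].")
  n <- ncol(ds$concentrations)
  n_noise <- round(f_n * n)
  if (n_noise == 0L) return(ds)
  untargeted <- setdiff(seq_len(n), seq_len(ds$n_targeted))
  if (n_noise > length(untargeted)) {
    abort("`f_n` would flag targeted metabolites as noise.")
  }
  with_preserved_rng({
    set.seed(child_seed(ds$seed, 5L))
    noise_idx <- sample(untargeted, n_noise)
  })
  mask <- rep(FALSE, n)
  mask[noise_idx] <- TRUE
  build_dataset(ds$data$time, ds$concentrations, ds$volumes, ds$epsilon,
                mask, ds$version, ds$seed, kinetics = ds$kinetics,
                n_targeted = ds$n_targeted)
}
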