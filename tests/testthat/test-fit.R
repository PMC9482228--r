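test_that("objective derivatives match the numerical oracle", {
  ds <- simulate_v1(n_metabolites = 8, n_timepoints = 7, cv = 0.2, seed = 71)
  mets <- names(ds$data)[-1]
  configs <- list(
    list(model = "pkm", ell = 8, transform = NULL, loss = NULL),
    list(model = "pkm", ell = 4, transform = "log10", loss = "cauchy"),
    list(model = "mix", ell = 4, transform = NULL, loss = NULL),
    list(model = "mix", ell = 4, transform = "none", loss = "max_linear")
  )
  set.seed(72)
  for (cfg in configs) {
    spec <- model_spec(ell = cfg$ell,
                       params = toy_parameter_table(mets[seq_len(cfg$ell)]),
                       transform = cfg$transform, loss = cfg$loss, n_starts = 1)
    obj <- volnorm:::build_objective(ds$data, spec, cfg$model)
    for (trial in 1:3) {
      par <- obj$lower + runif(obj$n_free) * (obj$upper - obj$lower)
      expect_equal(obj$jacobian_fn(par), numeric_jacobian(obj$residual_fn, par),
                   tolerance = 1e-4)
    }
  }
})

test_that("volumes and kinetics are recovered on clean data within bounds", {
  # noise-free four-metabolite toy data: everything identifiable
  ds <- simulate_v1(n_metabolites = 4, n_timepoints = 20, cv = 0, seed = 81)
  mets <- names(ds$data)[-1]
  spec <- model_spec(ell = 4, params = toy_parameter_table(mets), n_starts = 15)
  fit <- quiet_fit(ds$data, spec, model = "pkm", seed = 5)
  expect_lt(rrmse_volumes(ds$volumes, fit$volumes$volume), 0.05)
  # bound feasibility of every reported parameter
  expect_true(all(fit$volumes$volume >= spec$v_bounds[1] - 1e-10 &
                    fit$volumes$volume <= spec$v_bounds[2] + 1e-10))
  k <- tidy(fit)
  expect_true(all(k$estimate >= k$lower - 1e-10 & k$estimate <= k$upper + 1e-10))
  # loss is the minimum over starts
  expect_equal(fit$loss, min(fit$start_losses, na.rm = TRUE))
})

test_that("MIX with lambda = 1 reproduces the PKM fit exactly", {
  ds <- simulate_v1(n_metabolites = 6, n_timepoints = 10, cv = 0.2, seed = 91)
  mets <- names(ds$data)[-1]
  # identical hyperparameters so the only difference is the model label
  base <- list(ell = 4, params = toy_parameter_table(mets[1:4]),
               transform = "none", loss = "max_cauchy", n_starts = 6)
  pkm <- quiet_fit(ds$data, do.call(model_spec, base), model = "pkm", seed = 3)
  mix1 <- quiet_fit(ds$data, do.call(model_spec, c(base, lambda = 1)),
                    model = "mix", seed = 3)
  expect_identical(pkm$volumes$volume, mix1$volumes$volume)
  expect_identical(pkm$kinetics$estimate, mix1$kinetics$estimate)
  expect_identical(pkm$loss, mix1$loss)
})

test_that("fits are deterministic given the seed and monotone in the start budget", {
  ds <- simulate_v1(n_metabolites = 6, n_timepoints = 10, cv = 0.2, seed = 101)
  mets <- names(ds$data)[-1]
  mk <- function(n) model_spec(ell = 4, params = toy_parameter_table(mets[1:4]),
                               n_starts = n)
  f1 <- quiet_fit(ds$data, mk(5), model = "mix", seed = 17)
  f2 <- quiet_fit(ds$data, mk(5), model = "mix", seed = 17)
  expect_identical(f1$volumes, f2$volumes)
  expect_identical(f1$start_losses, f2$start_losses)
  # nested seed streams: more starts can only improve the best loss
  f10 <- quiet_fit(ds$data, mk(10), model = "mix", seed = 17)
  expect_identical(f10$start_losses[1:5], f1$start_losses)
  expect_lte(f10$loss, f1$loss)
})

test_that("duplicated metabolite columns get the same fitted kinetics", {
  ds <- simulate_v1(n_metabolites = 4, n_timepoints = 12, cv = 0, seed = 111)
  d <- ds$data
  d$caffeine_copy <- d$caffeine
  tk <- toy_kinetics()
  fixed <- list(
    caffeine = c(c0 = tk$c0[1], lag = 0, d = 0),
    caffeine_copy = c(c0 = tk$c0[1], lag = 0, d = 0)
  )
  d2 <- d[c("time", "caffeine", "caffeine_copy",
            "paraxanthine", "theobromine", "theophylline")]
  params <- kinetic_parameter_table(names(d2)[-1], fixed = c(
    fixed,
    list(paraxanthine = c(c0 = tk$c0[2], lag = 0, d = 0),
         theobromine = c(c0 = tk$c0[3], lag = 0, d = tk$d[3]),
         theophylline = c(c0 = tk$c0[4], lag = 0, d = tk$d[4]))
  ))
  fit <- quiet_fit(d2, model_spec(ell = 5, params = params, n_starts = 10),
                   model = "pkm", seed = 7)
  k <- tidy(fit)
  ka <- k$estimate[k$parameter == "k_a"]
  expect_equal(ka[k$metabolite[k$parameter == "k_a"] == "caffeine"],
               ka[k$metabolite[k$parameter == "k_a"] == "caffeine_copy"],
               tolerance = 1e-3)
})

test_that("degenerate constant-volume outcome warns instead of failing", {
  # two identical rows scaled: a dataset with no usable kinetic signal where
  # the optimizer can push volumes to a constant
  d <- constant_concentration_data(v = rep(1, 6), conc = c(1, 2, 3, 4))
  d$time <- 0:5
  spec <- model_spec(ell = 4, params = kinetic_parameter_table(names(d)[-1]),
                     n_starts = 2, v_bounds = c(0.9, 1.1))
  expect_warning(
    fit_volumes(d, spec, model = "mix", seed = 1),
    "no size effect"
  )
})

test_that("model specification and fit preconditions are validated", {
  ds <- simulate_v1(n_metabolites = 4, n_timepoints = 6, cv = 0.2, seed = 121)
  expect_error(model_spec(ell = 0), ">= 1")
  expect_error(model_spec(ell = 4, v_bounds = c(2, 1)), "lower < upper")
  expect_error(model_spec(ell = 4, lambda = 1.5), "lambda")
  expect_error(model_spec(ell = 3, kinetics = "subnetwork"), "exactly 2")
  spec1 <- model_spec(ell = 1)
  expect_error(fit_volumes(ds$data, spec1, model = "pkm"), "at least two")
  spec9 <- model_spec(ell = 9)
  expect_error(fit_volumes(ds$data, spec9, model = "pkm"), "exceeds")
})

test_that("subnetwork kinetics can be fitted jointly with volumes", {
  # parent/metabolite pair generated from the cascade
  t <- default_time_grid(12)
  truth <- c(k1 = 1.1, k2 = 0.4, k3 = 0.25, k4 = 0.5)
  cc <- subnetwork_concentrations(t, truth["k1"], truth["k2"], truth["k3"],
                                  truth["k4"], c0 = 2)
  V <- sample_volumes(12, seed = 132)
  d <- tibble::tibble(
    time = t,
    parent = cc$parent * V,
    metabolite = cc$metabolite * V
  )
  params <- subnetwork_parameter_table(fixed = c(c0 = 2))
  spec <- model_spec(ell = 2, kinetics = "subnetwork", params = params,
                     n_starts = 25)

  # the objective identifies the truth: zero loss at the generating values
  obj <- volnorm:::build_objective(d, spec, "pkm")
  expect_equal(sum(obj$residual_fn(c(truth, V))^2), 0)

  # local refinement from a perturbed start recovers rates and volumes
  set.seed(133)
  start <- pmin(pmax(c(truth, V) * exp(rnorm(16, 0, 0.15)), obj$lower),
                obj$upper)
  res <- minpack.lm::nls.lm(par = start, lower = obj$lower, upper = obj$upper,
                            fn = obj$residual_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  # the cascade has a shallow valley jointly shifting rates and volumes, so
  # refinement lands near -- not exactly on -- the generating values
  expect_lt(sum(res$fvec^2), 1e-4)
  expect_equal(unname(res$par[1:4]), unname(truth), tolerance = 0.1)

  # the multistart driver returns a feasible fit honouring the fixed c0
  fit <- quiet_fit(d, spec, model = "pkm", seed = 9)
  k <- tidy(fit)
  expect_equal(k$metabolite, rep("subnetwork", 5))
  expect_equal(k$estimate[k$parameter == "c0"], 2)
  expect_true(all(k$estimate >= k$lower - 1e-10 & k$estimate <= k$upper + 1e-10))
  expect_true(all(fit$volumes$volume >= 0.05 - 1e-10 &
                    fit$volumes$volume <= 4 + 1e-10))
})
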