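# Deterministic counter-based child seeds: one master seed spawns per-start
# (and, in the benchmark, per-cell / per-replicate) streams without coupling.
child_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) {
    s <- (s * 69069 + as.double(i) * 1000003 + 1) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_preserved_rng <- function(code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  force(code)
}

kinetic_par_names <- c("k_a", "k_e", "c0", "lag", "d")

#' Kinetic parameter bounds table
#'
#' Builds the per-metabolite table of kinetic parameter bounds and fixed
#' values consumed by [model_spec()].  Default bounds are
#' \eqn{(0,0,0,0,0) \le (k_a, k_e, c_0, lag, d) \le (3, 3, 5, 15, 3)}, the
#' same bounds used to sample kinetics in the synthetic benchmark.
#'
#' @param metabolites Character vector of modelled metabolite names.
#' @param k_a_bounds,k_e_bounds,c0_bounds,lag_bounds,d_bounds Length-2
#'   numeric lower/upper bounds.
#' @param fixed Optional named list: for each metabolite name, a named
#'   numeric vector of parameters to hold fixed (e.g.
#'   `list(met1 = c(c0 = 4, lag = 0, d = 0))`).
#'
#' @return A tibble with columns `metabolite`, `parameter`, `lower`,
#'   `upper`, `fixed`, `value`.
#' @examples
#' kinetic_parameter_table(c("caffeine", "paraxanthine"),
#'   fixed = list(caffeine = c(c0 = 4, lag = 0, d = 0)))
#' @export
kinetic_parameter_table <- function(metabolites,
                                    k_a_bounds = c(0, 3),
                                    k_e_bounds = c(0, 3),
                                    c0_bounds = c(0, 5),
                                    lag_bounds = c(0, 15),
                                    d_bounds = c(0, 3),
                                    fixed = NULL) {
  bounds <- rbind(k_a_bounds, k_e_bounds, c0_bounds, lag_bounds, d_bounds)
  if (any(bounds[, 1L] > bounds[, 2L])) abort("Lower bounds must not exceed upper bounds.")
  out <- tidyr::expand_grid(
    metabolite = metabolites,
    parameter = kinetic_par_names
  )
  out$lower <- rep(bounds[, 1L], times = length(metabolites))
  out$upper <- rep(bounds[, 2L], times = length(metabolites))
  out$fixed <- FALSE
  out$value <- NA_real_
  for (met in names(fixed)) {
    fv <- fixed[[met]]
    sel <- out$metabolite == met & out$parameter %in% names(fv)
    out$fixed[sel] <- TRUE
    out$value[sel] <- fv[out$parameter[sel]]
    bad <- sel & (out$value < out$lower - 1e-12 | out$value > out$upper + 1e-12)
    bad[is.na(bad)] <- FALSE
    if (any(bad)) abort(sprintf("Fixed value outside bounds for metabolite '%s'.", met))
  }
  out
}

#' Parameter table for the first-order mass-action subnetwork
#'
#' Bounds for the five parameters of the absorption cascade fitted by
#' [subnetwork_concentrations()]: the rate constants `k1`--`k4` and the
#' initial absorbable amount `c0`.
#'
#' @param k_bounds Length-2 bounds applied to all four rate constants.
#' @param c0_bounds Length-2 bounds for `c0`.
#' @param fixed Optional named numeric vector of parameters to hold fixed,
#'   e.g. `c(c0 = 1)`.
#'
#' @return A tibble in the same format as [kinetic_parameter_table()].
#' @export
subnetwork_parameter_table <- function(k_bounds = c(0, 3),
                                       c0_bounds = c(0, 5),
                                       fixed = NULL) {
  pars <- c("k1", "k2", "k3", "k4", "c0")
  out <- tibble::tibble(
    metabolite = "subnetwork",
    parameter = pars,
    lower = c(rep(k_bounds[1L], 4L), c0_bounds[1L]),
    upper = c(rep(k_bounds[2L], 4L), c0_bounds[2L]),
    fixed = FALSE,
    value = NA_real_
  )
  if (!is.null(fixed)) {
    sel <- out$parameter %in% names(fixed)
    out$fixed[sel] <- TRUE
    out$value[sel] <- fixed[out$parameter[sel]]
  }
  out
}

#' Normalization model specification
#'
#' Collects the hyperparameters of a PKM or MIX fit: how many metabolites
#' are kinetically modelled, which kinetic function is used, parameter and
#' volume bounds, transform, loss, scaling, the PKM/PQN weight
#' \eqn{\lambda}, and the Monte-Carlo multistart budget.
#'
#' Defaults left `NULL` are resolved per model at fit time: PKM uses the
#' `max_cauchy` loss with no transform; MIX uses the `cauchy` loss with a
#' `log10` transform, standard scaling, and \eqn{\lambda = 1/(\ell + 1)}.
#'
#' @param ell Number of kinetically modelled metabolites (the first `ell`
#'   metabolite columns of the data).  PKM needs `ell >= 2`; a "minimal"
#'   model keeps `ell` at the few well-constrained metabolites, a "full"
#'   model sets `ell` to the total number of metabolites.
#' @param kinetics `"bateman"` (one independent modified Bateman curve per
#'   modelled metabolite) or `"subnetwork"` (one shared first-order
#'   cascade for `ell = 2` metabolites).
#' @param params Parameter bounds table from [kinetic_parameter_table()] or
#'   [subnetwork_parameter_table()]; `NULL` uses default bounds with no
#'   fixed parameters.
#' @param v_bounds Length-2 lower/upper bounds for the fitted volumes
#'   (defaults to 0.05--4 uL, the finger-sweat range; use e.g.
#'   `c(0.01, 0.03)` mL for plasma).
#' @param transform,loss,scaling Transform `T`, loss `L`, and scaling `Z`
#'   (see [transform_values()], [loss_pkm()], [scale_values()]).
#' @param lambda Weight of the kinetic term, in \eqn{[0, 1]}; `NULL` means
#'   1 for PKM and \eqn{1/(\ell+1)} for MIX.
#' @param n_starts Number of Monte-Carlo multistart local optimizations;
#'   initial parameters are drawn uniformly between their bounds.
#' @param max_iter Maximum Levenberg--Marquardt iterations per start.
#' @param prescale If `TRUE`, each modelled metabolite column is divided by
#'   its maximum before fitting and the factor is folded back into the
#'   fitted `c0` (and `d`) afterwards; helps convergence when abundances
#'   span orders of magnitude.  Fixed `c0`/`d` values are then interpreted
#'   on the scaled (unit-maximum) scale.
#'
#' @return An object of class `volnorm_spec`.
#' @examples
#' model_spec(ell = 4, n_starts = 25)
#' @export
model_spec <- function(ell,
                       kinetics = c("bateman", "subnetwork"),
                       params = NULL,
                       v_bounds = c(0.05, 4),
                       transform = NULL,
                       loss = NULL,
                       scaling = "standard",
                       lambda = NULL,
                       n_starts = 100,
                       max_iter = 50,
                       prescale = FALSE) {
  kinetics <- match.arg(kinetics)
  if (!is.numeric(ell) || length(ell) != 1L || ell < 1) abort("`ell` must be >= 1.")
  if (kinetics == "subnetwork" && ell != 2L) {
    abort("The subnetwork kinetic model covers exactly 2 metabolites (`ell = 2`).")
  }
  if (length(v_bounds) != 2L || !(v_bounds[1L] < v_bounds[2L])) {
    abort("`v_bounds` must be c(lower, upper) with lower < upper.")
  }
  if (!is.null(lambda) && (lambda < 0 || lambda > 1)) abort("`lambda` must be in [0, 1].")
  if (!is.null(transform)) transform <- match.arg(transform, c("none", "log10"))
  if (!is.null(loss)) loss <- match.arg(loss, loss_kinds)
  scaling <- match.arg(scaling, c("standard", "mean"))
  structure(
    list(
      ell = as.integer(ell), kinetics = kinetics, params = params,
      v_bounds = as.numeric(v_bounds), transform = transform, loss = loss,
      scaling = scaling, lambda = lambda, n_starts = as.integer(n_starts),
      max_iter = as.integer(max_iter), prescale = isTRUE(prescale)
    ),
    class = "volnorm_spec"
  )
}

#' @export
print.volnorm_spec <- function(x, ...) {
  cat("<volnorm model spec>\n")
  cat("  ell:", x$ell, " kinetics:", x$kinetics, "\n")
  cat("  V bounds: [", x$v_bounds[1L], ",", x$v_bounds[2L], "]\n")
  cat("  transform:", x$transform %||% "(model default)",
      " loss:", x$loss %||% "(model default)",
      " scaling:", x$scaling, "\n")
  cat("  lambda:", if (is.null(x$lambda)) "(model default)" else x$lambda,
      " starts:", x$n_starts, "\n")
  invisible(x)
}

# Build the kinetic "units" (independent parameter blocks) for a fit.
# Each unit has a concentration function over its columns, analytic or
# numeric gradients, and its slice of the parameter table.
build_units <- function(spec, modelled) {
  ell <- spec$ell
  if (spec$kinetics == "bateman") {
    params <- spec$params %||% kinetic_parameter_table(modelled)
    lapply(seq_len(ell), function(j) {
      rows <- params[params$metabolite == modelled[j], , drop = FALSE]
      rows <- rows[match(kinetic_par_names, rows$parameter), , drop = FALSE]
      if (nrow(rows) != 5L || anyNA(rows$parameter)) {
        abort(sprintf("Parameter table lacks the 5 kinetic parameters for '%s'.", modelled[j]))
      }
      list(
        cols = j, par_names = kinetic_par_names,
        fn = bateman_p, grad = bateman_grad,
        lower = rows$lower, upper = rows$upper,
        fixed = rows$fixed, values = rows$value,
        label = modelled[j]
      )
    })
  } else {
    params <- spec$params %||% subnetwork_parameter_table()
    rows <- params[match(c("k1", "k2", "k3", "k4", "c0"), params$parameter), , drop = FALSE]
    list(list(
      cols = 1:2, par_names = c("k1", "k2", "k3", "k4", "c0"),
      fn = subnetwork_p, grad = NULL,
      lower = rows$lower, upper = rows$upper,
      fixed = rows$fixed, values = rows$value,
      label = "subnetwork"
    ))
  }
}

# Map the free-parameter vector to per-unit full parameter vectors + volumes.
unpack_par <- function(par, units, n_time) {
  n_units <- length(units)
  theta <- vector("list", n_units)
  pos <- 0L
  for (u in seq_len(n_units)) {
    un <- units[[u]]
    th <- un$values
    nf <- sum(!un$fixed)
    if (nf > 0L) {
      th[!un$fixed] <- par[pos + seq_len(nf)]
      pos <- pos + nf
    }
    theta[[u]] <- th
  }
  list(theta = theta, V = par[pos + seq_len(n_time)])
}

concentration_matrix <- function(theta, units, t, ell) {
  C <- matrix(0, nrow = length(t), ncol = ell)
  for (u in seq_along(units)) {
    C[, units[[u]]$cols] <- units[[u]]$fn(t, theta[[u]])
  }
  C
}

# d T(x)/d x for the shifted log10 transform (identity otherwise);
# preserves the shape of `x`.
transform_deriv <- function(x, kind) {
  if (kind == "none") x * 0 + 1 else 1 / ((x + 1e-8) * log(10))
}

#' Fit a PKM or MIX normalization model
#'
#' Jointly estimates kinetic parameters and per-time-point sample volumes
#' by minimizing the robust objective
#' \eqn{\mathcal{L}^{PKM}} (PKM) or
#' \eqn{\mathcal{L}^{PKM} + \mathcal{L}^{PQN}} (MIX), using bounded
#' Levenberg--Marquardt least squares with the robust loss folded into the
#' residuals, restarted from `n_starts` random initializations drawn
#' uniformly between the parameter bounds.  The first `spec$ell` metabolite
#' columns are modelled kinetically; for MIX, the PQN quotient vector is
#' computed from *all* metabolite columns (or supplied via `quotients`).
#'
#' If the fitted volume vector is (numerically) constant the model cannot
#' detect any size effect; the fit is returned with `no_size_effect = TRUE`
#' and a warning rather than an error, since this outcome is itself
#' informative.
#'
#' @param data A data frame with a `time` column and one strictly positive
#'   numeric column per metabolite; the first `spec$ell` columns are the
#'   kinetically modelled (targeted) metabolites.
#' @param spec A [model_spec()].
#' @param model `"pkm"` or `"mix"`.
#' @param quotients Optional [pqn_quotients()] result (or numeric vector)
#'   for the MIX quotient term; computed from `data` when `NULL`.
#' @param seed Integer seed controlling the Monte-Carlo starts; fits are
#'   fully reproducible given the seed.
#'
#' @return An object of class `volnorm_fit` with components `volumes`
#'   (tibble of `time`, `volume`), `kinetics` (tidy parameter tibble),
#'   `loss`, `start_losses`, `best_start`, and the resolved
#'   hyperparameters.  Supports [tidy()], [glance()], [augment()] and
#'   [autoplot()].
#' @examples
#' ds <- simulate_v1(n_metabolites = 4, seed = 1)
#' sp <- model_spec(ell = 4, params = toy_parameter_table(names(ds$data)[-1]),
#'                  n_starts = 5)
#' fit <- fit_volumes(ds$data, sp, model = "mix", seed = 1)
#' glance(fit)
#' @export
fit_volumes <- function(data, spec, model = c("pkm", "mix"),
                        quotients = NULL, seed = NULL) {
  model <- match.arg(model)
  obj <- build_objective(data, spec, model, quotients)
  fit_multistart(obj, spec, model, seed)
}

# Assemble the optimization problem for a PKM/MIX fit: bounds, the
# transformed-residual function whose sum of squares is the Eq.-9-style
# objective, and (where supported) its analytic Jacobian.  Separated from
# the multistart driver so the derivatives can be verified independently.
build_objective <- function(data, spec, model, quotients = NULL) {
  if (!inherits(spec, "volnorm_spec")) abort("`spec` must come from model_spec().")
  x <- check_mass_ts(data)
  n_time <- length(x$time)
  ell <- spec$ell
  if (ell > ncol(x$m)) abort("`ell` exceeds the number of metabolite columns.")
  if (model == "pkm" && ell < 2L) {
    abort("PKM needs the kinetics of at least two metabolites (`ell >= 2`).")
  }
  if (n_time < 2L) abort("Need at least two time points.")

  transform <- spec$transform %||% if (model == "pkm") "none" else "log10"
  loss <- spec$loss %||% if (model == "pkm") "max_cauchy" else "cauchy"
  lambda <- if (model == "pkm") 1 else spec$lambda %||% lambda_weight(ell)
  scaling <- spec$scaling

  modelled <- x$metabolites[seq_len(ell)]
  M <- x$m[, seq_len(ell), drop = FALSE]
  col_scale <- rep(1, ell)
  if (spec$prescale) {
    col_scale <- apply(M, 2L, max)
    M <- sweep(M, 2L, col_scale, "/")
  }

  q <- NULL
  if (model == "mix" && lambda < 1) {
    q <- quotients %||% pqn_quotients(data)
    if (inherits(q, "volnorm_pqn")) q <- q$quotient
    if (length(q) != n_time) abort("`quotients` length must match the number of time points.")
    if (any(q < 0)) abort("Quotients must be non-negative.")
  }

  units <- build_units(spec, modelled)
  lower <- c(unlist(lapply(units, function(u) u$lower[!u$fixed])), rep(spec$v_bounds[1L], n_time))
  upper <- c(unlist(lapply(units, function(u) u$upper[!u$fixed])), rep(spec$v_bounds[2L], n_time))
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    abort("All parameter bounds must be finite (start values are drawn between them).")
  }
  n_free <- length(lower)
  t <- x$time
  tm <- transform_values(M, transform)
  sql <- sqrt(lambda)
  q_active <- !is.null(q)
  if (q_active) {
    tq <- transform_values(q, transform)
    # constant quotients carry no size-effect signal; their standardised
    # shape is taken as flat rather than undefined
    zq <- if (scaling == "standard" && sd_pop(tq) == 0) {
      rep(0, n_time)
    } else {
      scale_values(tq, scaling, transform)
    }
    sqml <- sqrt(1 - lambda)
  }

  residual_fn <- function(par) {
    up <- unpack_par(par, units, n_time)
    C <- concentration_matrix(up$theta, units, t, ell)
    P <- C * up$V
    f <- sql * (tm - transform_values(P, transform))
    r <- robust_residual(as.vector(f), loss, ref = as.vector(tm))
    if (q_active) {
      u <- transform_values(up$V, transform)
      vu <- var_pop(u)
      r2 <- if (vu < 1e-300) {
        rep(0, n_time) # constant volume candidate: quotient term vanishes
      } else if (scaling == "standard") {
        # sqrt((1-lambda) Var(u)) * (Z(u) - Z(q)) simplifies to this form
        sqml * ((u - mean(u)) - zq * sqrt(vu))
      } else {
        sqml * sqrt(vu) * (scale_values(u, "mean", transform) - zq)
      }
      r <- c(r, robust_residual(r2, loss))
    }
    r
  }

  use_analytic <- spec$kinetics == "bateman" && (!q_active || scaling == "standard")
  jacobian_fn <- NULL
  if (use_analytic) {
    jacobian_fn <- function(par) {
      up <- unpack_par(par, units, n_time)
      C <- concentration_matrix(up$theta, units, t, ell)
      P <- C * up$V
      f <- sql * (tm - transform_values(P, transform))
      psi <- robust_residual_deriv(as.vector(f), loss, ref = as.vector(tm))
      tp1 <- transform_deriv(P, transform) # matrix
      n_res <- n_time * ell + if (q_active) n_time else 0L
      J <- matrix(0, nrow = n_res, ncol = n_free)
      v_off <- n_free - n_time
      # PKM rows: residual index (i, j) -> row (j - 1) * n_time + i
      pos <- 0L
      for (u in seq_along(units)) {
        un <- units[[u]]
        nf <- sum(!un$fixed)
        if (nf > 0L) {
          g <- un$grad(t, up$theta[[u]]) # n_time x 5
          j <- un$cols
          rows <- (j - 1L) * n_time + seq_len(n_time)
          dP <- g[, !un$fixed, drop = FALSE] * up$V # dP/dtheta = V * dC/dtheta
          J[rows, pos + seq_len(nf)] <- -sql * tp1[, j] * dP
          pos <- pos + nf
        }
      }
      for (j in seq_len(ell)) {
        rows <- (j - 1L) * n_time + seq_len(n_time)
        J[cbind(rows, v_off + seq_len(n_time))] <- -sql * tp1[, j] * C[, j]
      }
      J[seq_len(n_time * ell), ] <- J[seq_len(n_time * ell), ] * psi
      if (q_active) {
        u_t <- transform_values(up$V, transform)
        vu <- var_pop(u_t)
        if (vu >= 1e-300) {
          su <- sqrt(vu)
          f2 <- sqml * ((u_t - mean(u_t)) - zq * su)
          psi2 <- robust_residual_deriv(f2, loss)
          du <- transform_deriv(up$V, transform)
          cu <- (u_t - mean(u_t)) / (n_time * su)
          # d f2_i / d u_k = sqml * (delta_ik - 1/n - zq_i * cu_k)
          A <- -sqml * (outer(rep(1, n_time), rep(1 / n_time, n_time)) +
                          outer(zq, cu))
          diag(A) <- diag(A) + sqml
          A <- A * psi2 # row scale
          A <- sweep(A, 2L, du, "*")
          J[n_time * ell + seq_len(n_time), v_off + seq_len(n_time)] <- A
        }
      }
      J
    }
  }

  list(
    residual_fn = residual_fn, jacobian_fn = jacobian_fn,
    lower = lower, upper = upper, n_free = n_free,
    units = units, t = t, n_time = n_time, ell = ell,
    transform = transform, loss = loss, lambda = lambda, scaling = scaling,
    q = q, modelled = modelled, col_scale = col_scale, data = data
  )
}

# Monte-Carlo multistart driver: runs bounded Levenberg-Marquardt from
# n_starts uniform random initializations and keeps the lowest objective
# (ties broken by the lowest start index).
fit_multistart <- function(obj, spec, model, seed) {
  lower <- obj$lower
  upper <- obj$upper
  n_free <- obj$n_free
  n_time <- obj$n_time
  units <- obj$units
  modelled <- obj$modelled
  seed <- seed %||% 1L
  control <- minpack.lm::nls.lm.control(
    maxiter = spec$max_iter, ftol = 1e-8, ptol = 1e-8, gtol = 1e-8
  )
  starts <- seq_len(spec$n_starts)
  best <- NULL
  best_loss <- Inf
  best_start <- NA_integer_
  start_losses <- rep(NA_real_, spec$n_starts)
  diagnostics <- character(spec$n_starts)
  with_preserved_rng({
    for (s in starts) {
      set.seed(child_seed(seed, 7L, s))
      init <- lower + runif(n_free) * (upper - lower)
      res <- tryCatch(
        minpack.lm::nls.lm(
          par = init, lower = lower, upper = upper,
          fn = obj$residual_fn, jac = obj$jacobian_fn, control = control
        ),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        diagnostics[s] <- conditionMessage(res)
        next
      }
      l <- sum(res$fvec^2)
      start_losses[s] <- l
      if (l < best_loss) {
        best_loss <- l
        best <- res
        best_start <- s
      }
    }
  })
  if (is.null(best)) {
    abort(c("Optimization failed on every Monte-Carlo start.",
            stats::na.omit(unique(diagnostics))[1:min(3, length(diagnostics))]))
  }

  up <- unpack_par(best$par, units, n_time)
  V_hat <- up$V
  kin <- purrr::map2_dfr(units, up$theta, function(un, th) {
    est <- th
    if (spec$prescale && un$label %in% modelled) {
      sc <- obj$col_scale[match(un$label, modelled)]
      est[un$par_names %in% c("c0", "d")] <- est[un$par_names %in% c("c0", "d")] * sc
    }
    tibble::tibble(
      metabolite = un$label, parameter = un$par_names,
      estimate = est, lower = un$lower, upper = un$upper, fixed = un$fixed
    )
  })

  no_size_effect <- var_pop(transform_values(V_hat, obj$transform)) < 1e-10
  if (no_size_effect) {
    warn("Fitted volumes are (numerically) constant: no size effect detected in this data set.")
  }

  structure(
    list(
      volumes = tibble::tibble(time = obj$t, volume = V_hat),
      kinetics = kin,
      loss = best_loss,
      start_losses = start_losses,
      best_start = best_start,
      model = model,
      ell = obj$ell,
      transform = obj$transform,
      loss_kind = obj$loss,
      scaling = obj$scaling,
      lambda = obj$lambda,
      n_starts = spec$n_starts,
      seed = seed,
      v_bounds = spec$v_bounds,
      quotients = obj$q,
      data = obj$data,
      modelled = modelled,
      no_size_effect = no_size_effect,
      info = best$info
    ),
    class = "volnorm_fit"
  )
}
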