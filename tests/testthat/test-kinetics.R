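test_that("Bateman curve matches direct evaluation and its boundary behaviour", {
  # high-precision oracle: b(1) = 1 * 2 / (1 - 2) * (e^-2 - e^-1)
  expect_equal(bateman(1, k_a = 2, k_e = 1, c0 = 1, lag = 0, d = 0),
               2 * (exp(-1) - exp(-2)), tolerance = 1e-12)
  # b vanishes at t = lag, leaving the baseline
  expect_equal(bateman(5, k_a = 1, k_e = 2, c0 = 1, lag = 5, d = 0.3), 0.3)
  # c0 = 0 forces the kinetic part to zero at any time
  expect_equal(bateman(c(-3, 0, 2, 17), k_a = 0.7, k_e = 2, c0 = 0, d = 0.7),
               rep(0.7, 4))
  expect_error(bateman(1, k_a = NaN, k_e = 1, c0 = 1), "finite")
  expect_error(bateman(Inf, k_a = 1, k_e = 2, c0 = 1), "finite")
})

test_that("Bateman curve sits at baseline before lag for random parameters", {
  set.seed(11)
  for (i in 1:50) {
    p <- runif(5, c(0.01, 0.01, 0, 0, 0), c(3, 3, 5, 15, 3))
    if (abs(p[1] - p[2]) < 1e-3) p[2] <- p[2] + 0.1
    t_before <- runif(5, -5, p[4] - 1e-6)
    expect_equal(bateman(t_before, p[1], p[2], p[3], p[4], p[5]),
                 rep(p[5], 5), tolerance = 1e-12)
    # and never below baseline anywhere
    t_any <- runif(20, -5, 30)
    expect_true(all(bateman(t_any, p[1], p[2], p[3], p[4], p[5]) >= p[5] - 1e-12))
  }
})

test_that("equal-rate limit branch is continuous with the two-exponential form", {
  t <- seq(0, 10, by = 0.5)
  # analytic limit oracle at k_e = k_a
  limit <- function(t, k, c0) c0 * k * t * exp(-k * t)
  for (k in c(0.3, 1, 2.5)) {
    # two-exponential branch evaluated just off the pole approaches the limit
    near <- bateman(t, k_a = k, k_e = k + 1e-4, c0 = 1.7)
    expect_equal(near, pmax(limit(t, k, 1.7), 0), tolerance = 1e-3)
    # no jump across the branch-switch threshold
    below <- bateman(t, k_a = k, k_e = k + 0.9e-9, c0 = 1.7)
    above <- bateman(t, k_a = k, k_e = k + 1.1e-9, c0 = 1.7)
    expect_lt(max(abs(below - above)), 1e-6)
  }
})

test_that("Bateman gradient matches central differences", {
  t <- seq(0.2, 14, length.out = 9)
  set.seed(21)
  for (i in 1:20) {
    p <- runif(5, c(0.05, 0.05, 0.1, 0, 0), c(3, 3, 5, 10, 3))
    if (abs(p[1] - p[2]) < 1e-3) p[2] <- p[2] + 0.05
    ga <- volnorm:::bateman_grad(t, p)
    gn <- numeric_jacobian(function(q) volnorm:::bateman_p(t, q), p)
    # rows where the curve is clamped to baseline have zero kinetic gradient;
    # exclude points straddling the clamp boundary under perturbation
    b <- volnorm:::bateman_p(t, p) - p[5]
    ok <- b > 1e-4
    expect_equal(unname(ga[ok, , drop = FALSE]), gn[ok, , drop = FALSE],
                 tolerance = 1e-5)
  }
})

test_that("subnetwork closed form matches a numerical ODE oracle", {
  skip_if_not_installed("deSolve")
  ode_oracle <- function(t, k1, k2, k3, k4, c0) {
    rhs <- function(t, y, parms) {
      with(as.list(c(y, parms)), list(c(
        dA = -k1 * A,
        dP = k1 * A - (k2 + k3) * P,
        dM = k2 * P - k4 * M,
        dE = k3 * P + k4 * M
      )))
    }
    out <- deSolve::ode(
      y = c(A = c0, P = 0, M = 0, E = 0), times = c(0, t), func = rhs,
      parms = list(k1 = k1, k2 = k2, k3 = k3, k4 = k4),
      rtol = 1e-10, atol = 1e-12
    )
    out[-1, , drop = FALSE]
  }

  # spec'd example point
  t <- c(0.5, 1, 2, 5, 10)
  cc <- subnetwork_concentrations(t, k1 = 1, k2 = 0.3, k3 = 0.2, k4 = 0.4, c0 = 1)
  oo <- ode_oracle(t, 1, 0.3, 0.2, 0.4, 1)
  expect_equal(cc$parent, unname(oo[, "P"]), tolerance = 1e-8)
  expect_equal(cc$metabolite, unname(oo[, "M"]), tolerance = 1e-8)

  # random parameter draws
  set.seed(31)
  worst <- 0
  for (i in 1:100) {
    k <- runif(4, 0.05, 3)
    cc <- subnetwork_concentrations(t, k[1], k[2], k[3], k[4], c0 = 2)
    oo <- ode_oracle(t, k[1], k[2], k[3], k[4], 2)
    worst <- max(worst, max(abs(cc$parent - oo[, "P"])),
                 max(abs(cc$metabolite - oo[, "M"])))
  }
  expect_lt(worst, 1e-7)
})

test_that("subnetwork conserves mass and handles degenerate rates", {
  # no absorption: everything stays zero
  cc <- subnetwork_concentrations(0:10, 0, 0, 0, 0, c0 = 1)
  expect_equal(cc$parent, rep(0, 11))
  expect_equal(cc$metabolite, rep(0, 11))

  # closed-form amount eliminated is non-negative and non-decreasing
  t <- seq(0, 20, by = 0.25)
  cc <- subnetwork_concentrations(t, 1.2, 0.4, 0.3, 0.6, c0 = 3)
  A <- 3 * exp(-1.2 * t)
  elim <- 3 - A - cc$parent - cc$metabolite
  expect_true(all(elim >= -1e-10))
  expect_true(all(diff(elim) >= -1e-10))

  # coinciding eigenvalues are perturbed, not NaN
  same <- subnetwork_concentrations(t, 1, 0.5, 0.5, 1, c0 = 1)
  expect_true(all(is.finite(same$parent)) && all(is.finite(same$metabolite)))

  expect_error(subnetwork_concentrations(1, -0.1, 0, 0, 0), "non-negative")
})
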