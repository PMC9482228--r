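#' Modified Bateman concentration curve
#'
#' Evaluates the two-exponential absorption--elimination curve used to model
#' metabolite concentration time series,
#' \deqn{b(t) = c_0 \frac{k_a}{k_e - k_a}\left(e^{-k_a (t - lag)} -
#'   e^{-k_e (t - lag)}\right),}
#' clamped to the baseline offset where the core term is negative:
#' \eqn{F(t) = b(t) + d} if \eqn{b(t) \ge 0}, else \eqn{F(t) = d}.
#' The `lag` parameter shifts the absorption start along the time axis and
#' `d` is a constant baseline concentration.  Near the removable pole
#' \eqn{k_a = k_e} the analytic limit
#' \eqn{b(t) = c_0 k_a (t - lag) e^{-k_a (t - lag)}} is used.
#'
#' @param t Numeric vector of times (h).  May be any finite real values;
#'   for `t < lag` the curve sits at the baseline `d` (when `k_a != k_e`).
#' @param k_a Absorption rate constant (1/h, >= 0).
#' @param k_e Elimination rate constant (1/h, >= 0).
#' @param c0 Amount absorbed over volume of distribution (concentration
#'   units, >= 0).
#' @param lag Absorption start time (h, >= 0).
#' @param d Baseline concentration offset (concentration units, >= 0).
#'
#' @return Numeric vector of concentrations, same length as `t`.
#' @examples
#' bateman(seq(0, 15, length.out = 5), k_a = 1.2, k_e = 0.5, c0 = 4)
#' @export
bateman <- function(t, k_a, k_e, c0, lag = 0, d = 0) {
  p <- c(k_a = k_a, k_e = k_e, c0 = c0, lag = lag, d = d)
  if (!all(is.finite(p))) {
    abort("Bateman parameters must be finite numbers.")
  }
  if (!all(is.finite(t))) {
    abort("`t` must be finite.")
  }
  tau <- t - lag
  if (abs(k_e - k_a) < 1e-9) {
    b <- c0 * k_a * tau * exp(-k_a * tau)
  } else {
    b <- c0 * k_a / (k_e - k_a) * (exp(-k_a * tau) - exp(-k_e * tau))
  }
  ifelse(b >= 0, b + d, d)
}

# Vector-parameter form used by the fitting engine: p = (k_a, k_e, c0, lag, d).
bateman_p <- function(t, p) {
  bateman(t, p[1L], p[2L], p[3L], p[4L], p[5L])
}

# Analytic partial derivatives of bateman() with respect to the five kinetic
# parameters.  Returns a length(t) x 5 matrix (columns k_a, k_e, c0, lag, d).
# Where b(t) < 0 the curve is flat at d, so only the d-column is non-zero.
# Near k_a = k_e the elimination rate is nudged off the pole; the curve itself
# is continuous there so the approximation only affects a measure-zero set.
bateman_grad <- function(t, p) {
  k_a <- p[1L]; k_e <- p[2L]; c0 <- p[3L]; lag <- p[4L]; d <- p[5L]
  if (abs(k_e - k_a) < 1e-9) k_e <- k_a + 1e-6
  tau <- t - lag
  ea <- exp(-k_a * tau)
  ee <- exp(-k_e * tau)
  dk <- k_e - k_a
  b <- c0 * k_a / dk * (ea - ee)
  on <- as.numeric(b >= 0)
  g <- cbind(
    k_a = c0 * (k_e / dk^2 * (ea - ee) - k_a / dk * tau * ea),
    k_e = c0 * (-k_a / dk^2 * (ea - ee) + k_a / dk * tau * ee),
    c0  = k_a / dk * (ea - ee),
    lag = c0 * k_a / dk * (k_a * ea - k_e * ee),
    d   = rep(1, length(t))
  )
  g[, 1:4] <- g[, 1:4] * on
  g
}

#' First-order mass-action absorption cascade
#'
#' Closed-form concentrations for the linear cascade used to model caffeine
#' and one of its degradation products: an absorbable pool \eqn{A} feeds the
#' parent compound, which is partly converted to the metabolite and partly
#' eliminated, and the metabolite is eliminated in turn:
#' \deqn{dA/dt = -k_1' A,\quad
#'   dP/dt = k_1' A - (k_2' + k_3') P,\quad
#'   dM/dt = k_2' P - k_4' M,}
#' with \eqn{A(0) = c_0}, \eqn{P(0) = M(0) = 0}.  The parent's effective
#' absorption and elimination constants are \eqn{k_a = k_1'} and
#' \eqn{k_e = k_2' + k_3'}.  Coinciding eigenvalues are perturbed by a
#' negligible amount to keep the three-exponential solution numerically
#' stable.
#'
#' @param t Numeric vector of times (h, >= 0 for physical interpretation).
#' @param k1,k2,k3,k4 First-order rate constants (1/h, >= 0): absorption,
#'   conversion parent -> metabolite, parent elimination, metabolite
#'   elimination.
#' @param c0 Initial absorbable amount (concentration units, >= 0).
#'
#' @return A tibble with columns `time`, `parent`, and `metabolite`.
#' @examples
#' subnetwork_concentrations(0:10, k1 = 1, k2 = 0.3, k3 = 0.2, k4 = 0.4, c0 = 1)
#' @export
subnetwork_concentrations <- function(t, k1, k2, k3, k4, c0 = 1) {
  ks <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, c0 = c0)
  if (!all(is.finite(ks))) abort("Rate constants must be finite.")
  if (any(ks < 0)) abort("Rate constants and `c0` must be non-negative.")
  kE <- k2 + k3
  # separate coinciding eigenvalues (measure-zero case)
  if (abs(kE - k1) < 1e-9) kE <- k1 + 1e-9
  if (abs(k4 - k1) < 1e-9) k4 <- k1 + 2e-9
  if (abs(k4 - kE) < 1e-9) k4 <- kE + 1e-9
  e1 <- exp(-k1 * t)
  eE <- exp(-kE * t)
  e4 <- exp(-k4 * t)
  parent <- c0 * k1 / (kE - k1) * (e1 - eE)
  metab <- c0 * k1 * k2 * (
    e1 / ((kE - k1) * (k4 - k1)) +
      eE / ((k1 - kE) * (k4 - kE)) +
      e4 / ((k1 - k4) * (kE - k4))
  )
  tibble::tibble(
    time = t,
    parent = pmax(parent, 0),
    metabolite = pmax(metab, 0)
  )
}

# Vector-parameter form for the fitting engine: p = (k1, k2, k3, k4, c0);
# returns a length(t) x 2 concentration matrix (parent, metabolite).
subnetwork_p <- function(t, p) {
  cc <- subnetwork_concentrations(t, p[1L], p[2L], p[3L], p[4L], p[5L])
  cbind(cc$parent, cc$metabolite)
}
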