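#' Data transformation applied before loss calculation
#'
#' Either the identity or a shifted decadic logarithm,
#' \eqn{T(x) = \log_{10}(x + 10^{-8})}.  The small additive constant (the
#' size of the optimizer precision) keeps zero abundances finite.  The log
#' transform treats measurement error as multiplicative, which matches
#' LC-MS abundance data and log-normally distributed sample volumes.
#'
#' @param x Numeric vector or matrix, non-negative under `"log10"`.
#' @param kind `"none"` or `"log10"`.
#'
#' @return Transformed values, same shape as `x`.
#' @examples
#' transform_values(c(0, 1, 100), "log10")
#' @export
transform_values <- function(x, kind = c("none", "log10")) {
  kind <- match.arg(kind)
  if (kind == "none") return(x)
  if (any(x < 0)) abort("Negative values cannot be log10-transformed.")
  log10(x + 1e-8)
}

#' Scaling applied to transformed quotient and volume vectors
#'
#' Standard scaling centres and divides by the population standard
#' deviation, \eqn{Z(x) = (x - \mathrm{mean}(x))/\mathrm{Std}(x)}.  Mean
#' scaling centres only: it subtracts the mean under a log transform
#' (location shift = scale factor in raw space) and divides by the mean
#' otherwise.  Standard scaling makes the quotient vector's *shape* the
#' only information passed on, which is what keeps the MIX model robust to
#' the quotient-shrinkage caused by volume-independent (noise) features.
#'
#' @param x Numeric vector (length >= 2 for standard scaling).
#' @param kind `"standard"` or `"mean"`.
#' @param transform The transform (`"none"` or `"log10"`) that produced
#'   `x`; only mean scaling depends on it.
#'
#' @return Scaled numeric vector.
#' @examples
#' scale_values(c(1, 2, 3), "standard")
#' @export
scale_values <- function(x, kind = c("standard", "mean"),
                         transform = c("none", "log10")) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  if (kind == "standard") {
    if (length(x) < 2L) abort("Standard scaling needs at least two values.")
    s <- sd_pop(x)
    if (s == 0) abort("Degenerate series: standard deviation is zero.")
    return((x - mean(x)) / s)
  }
  if (transform == "log10") x - mean(x) else x / mean(x)
}

# Population (n-denominator) standard deviation / variance, used throughout
# for scalings and goodness measures.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
var_pop <- function(x) mean((x - mean(x))^2)

#' Weight of the kinetic loss term in the MIX objective
#'
#' The MIX objective balances one kinetic (PKM) term per modelled
#' metabolite against a single quotient (PQN) term; weighting each term by
#' the number of fitted data-point blocks gives \eqn{\lambda = 1/(\ell+1)}
#' for \eqn{\ell} kinetically modelled metabolites.  \eqn{\lambda = 1}
#' recovers a pure PKM model.
#'
#' @param ell Number of kinetically modelled metabolites (>= 1).
#' @return The weight \eqn{\lambda \in (0, 1]}.
#' @examples
#' lambda_weight(4) # 0.2
#' @export
lambda_weight <- function(ell) {
  if (!is.numeric(ell) || length(ell) != 1L || !is.finite(ell) || ell < 1) {
    abort("`ell` must be a single number >= 1.")
  }
  1 / (ell + 1)
}

# --- robust loss machinery ---------------------------------------------------
#
# The objective is a sum of L[z_k] terms where z_k is a squared weighted
# residual and L is either the identity or the Cauchy loss rho(z) = ln(1+z).
# For least-squares optimization each term is folded into a single
# transformed residual r' = sign(f) * sqrt(L(z)), so that sum(r'^2) equals
# the objective exactly.
#
# "max" variants replace the squared absolute residual f^2 by
# max(f^2, g^2) with g the residual relative to the transformed datum,
# guarded where |T(M)| < 1e-12.

loss_kinds <- c("cauchy", "max_cauchy", "max_linear")

# f: weighted absolute residuals; ref: transformed data values T(M) used for
# the relative residual of the max variants (NULL -> absolute only).
robust_residual <- function(f, loss, ref = NULL) {
  z <- f^2
  if (loss %in% c("max_cauchy", "max_linear") && !is.null(ref)) {
    denom <- ifelse(abs(ref) < 1e-12, Inf, ref)
    z <- pmax(z, (f / denom)^2)
  }
  r <- if (loss == "max_linear") sqrt(z) else sqrt(log1p(z))
  sign(f) * r
}

# d r'/d f for the chain rule in the analytic Jacobian.  Returns the factor
# multiplying df/dpar row-wise.
robust_residual_deriv <- function(f, loss, ref = NULL) {
  c2 <- rep(1, length(f))
  z <- f^2
  if (loss %in% c("max_cauchy", "max_linear") && !is.null(ref)) {
    denom <- ifelse(abs(ref) < 1e-12, Inf, ref)
    zrel <- (f / denom)^2
    rel <- zrel > z
    c2[rel] <- 1 / denom[rel]^2
    z <- pmax(z, zrel)
  }
  if (loss == "max_linear") return(sqrt(c2))
  rho <- log1p(z)
  out <- sqrt(c2)
  big <- z > 1e-20
  out[big] <- (c2[big] * abs(f[big])) / ((1 + z[big]) * sqrt(rho[big]))
  out
}

#' Kinetic (PKM) loss term
#'
#' Sums the robust loss of the weighted squared residuals between
#' transformed measured masses and transformed model masses,
#' \eqn{\sum_{ij} L[\lambda (T(\tilde M_{ij}) - T(C_{ij} V_i))^2]}.
#'
#' @param M Measured mass matrix (time points x modelled metabolites).
#' @param C Model concentration matrix, same shape as `M`.
#' @param V Volume vector, one entry per time point.
#' @param transform Transform `T` (`"none"` or `"log10"`).
#' @param loss Loss `L`: `"cauchy"` (\eqn{\rho(z) = \ln(1+z)} of the
#'   squared absolute residual), `"max_cauchy"` (Cauchy of the maximum of
#'   squared absolute and relative residuals), or `"max_linear"`.
#' @param lambda Weight of the kinetic term, in \eqn{[0, 1]}.
#'
#' @return The scalar loss value.
#' @export
loss_pkm <- function(M, C, V, transform = "none", loss = "max_cauchy",
                     lambda = 1) {
  M <- as.matrix(M); C <- as.matrix(C)
  if (!all(dim(M) == dim(C)) || nrow(M) != length(V)) {
    abort("`M`, `C` and `V` dimensions do not agree.")
  }
  loss <- match.arg(loss, loss_kinds)
  tm <- transform_values(M, transform)
  tcv <- transform_values(C * V, transform)
  f <- sqrt(lambda) * (tm - tcv)
  sum(robust_residual(f, loss, ref = tm)^2)
}

#' Quotient (PQN) loss term
#'
#' Sums the robust loss of the weighted squared differences between the
#' scaled, transformed volume candidate and the scaled, transformed PQN
#' quotients,
#' \eqn{\sum_i L[(1-\lambda)(ZT(V)_i - ZT(Q)_i)^2\,\mathrm{Var}(T(V))]}.
#' The \eqn{\mathrm{Var}(T(V))} factor is computed from the current volume
#' iterate; it couples the scale of this term to the kinetic term, which is
#' what lets standard scaling carry information.  A constant volume
#' candidate makes the term vanish (no detectable size effect).
#'
#' @param V Volume vector (length >= 2).
#' @param q PQN quotient vector (same length) or a [pqn_quotients()] result.
#' @param transform Transform `T` applied to both vectors.
#' @param scaling Scaling `Z` (`"standard"` or `"mean"`).
#' @inheritParams loss_pkm
#'
#' @return The scalar loss value.
#' @export
loss_pqn <- function(V, q, transform = "log10", scaling = "standard",
                     loss = "cauchy", lambda = NULL) {
  if (inherits(q, "volnorm_pqn")) q <- q$quotient
  if (length(V) != length(q)) abort("`V` and `q` must have the same length.")
  if (length(V) < 2L) abort("Need at least two time points (variance undefined).")
  loss <- match.arg(loss, loss_kinds)
  lambda <- lambda %||% 0.5
  if (lambda >= 1) return(0)
  u <- transform_values(V, transform)
  vu <- var_pop(u)
  if (vu == 0) return(0)
  zu <- scale_values(u, scaling, transform)
  zq <- scale_values(transform_values(q, transform), scaling, transform)
  f <- sqrt((1 - lambda) * vu) * (zu - zq)
  sum(robust_residual(f, loss)^2)
}
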