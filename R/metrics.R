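#' Goodness-of-normalization measures
#'
#' `rmse_volumes()` is the population standard deviation of the residuals
#' between true and fitted volume vectors -- an absolute measure of how
#' well sample volumes are recovered (volume units).  `rrmse_volumes()` is
#' the population standard deviation of the ratio
#' \eqn{r_i = V^{true}_i / V^{fit}_i} divided by its mean -- a scale-free
#' measure of how well volumes are recovered *relative to each other*.
#' Because rRMSE is invariant to a common scale factor on the fitted
#' vector, it can evaluate PQN quotients, which determine volumes only up
#' to an unknown reference volume; no RMSE can be calculated for PQN.
#'
#' @param v_true True volume vector.
#' @param v_fit Fitted volume vector (or PQN quotients for
#'   `rrmse_volumes()`); strictly positive for the ratio-based measure.
#'
#' @return A scalar.
#' @examples
#' rmse_volumes(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' rrmse_volumes(c(1, 2, 4), c(1, 1, 1))
#' @export
rmse_volumes <- function(v_true, v_fit) {
  check_metric_args(v_true, v_fit, positive = FALSE)
  sd_pop(v_true - v_fit)
}

#' @rdname rmse_volumes
#' @export
rrmse_volumes <- function(v_true, v_fit) {
  check_metric_args(v_true, v_fit, positive = TRUE)
  r <- v_true / v_fit
  sd_pop(r) / mean(r)
}

check_metric_args <- function(v_true, v_fit, positive) {
  if (length(v_true) != length(v_fit)) abort("Vectors must have the same length.")
  if (length(v_true) < 2L) abort("Need at least two time points.")
  if (positive && any(v_fit <= 0)) abort("Fitted values must be strictly positive.")
  invisible(NULL)
}

#' Scaled error of PQN quotients against true volumes
#'
#' Diagnoses how well mean and standard scaling align the (transformed)
#' quotient vector with the (transformed) true volume vector.  The
#' mean-scaled error accumulates
#' \eqn{ZT(Q)_i - ZT(V)_i} under mean scaling, the standard-scaled error
#' accumulates the same difference under standard scaling multiplied by
#' \eqn{\mathrm{Std}(T(V))} -- the multiplication makes the two
#' comparable, since standard scaling would otherwise always favour the
#' smaller-spread vector.  With the log transform both scalings centre
#' their arguments, so the signed sums are zero by construction;
#' `absolute = TRUE` sums element-wise absolute deviations instead, which
#' is the informative "error size" variant used for plotting and for
#' comparing the two scalings.
#'
#' @param q PQN quotient vector or [pqn_quotients()] result.
#' @param v_true True volume vector, same length.
#' @param transform Transform `T`, by default `"log10"`.
#' @param absolute If `TRUE`, sum absolute element-wise deviations.
#'
#' @return A tibble with columns `mean_scaled` and `standard_scaled`.
#' @examples
#' scaled_errors(c(1, 2, 3), c(1, 2, 3))
#' @export
scaled_errors <- function(q, v_true, transform = "log10", absolute = FALSE) {
  if (inherits(q, "volnorm_pqn")) q <- q$quotient
  if (length(q) != length(v_true)) abort("Vectors must have the same length.")
  if (length(q) < 2L) abort("Need at least two time points.")
  tq <- transform_values(q, transform)
  tv <- transform_values(v_true, transform)
  dm <- scale_values(tq, "mean", transform) - scale_values(tv, "mean", transform)
  dstd <- (scale_values(tq, "standard", transform) -
             scale_values(tv, "standard", transform)) * sd_pop(tv)
  agg <- if (absolute) function(x) sum(abs(x)) else sum
  tibble::tibble(mean_scaled = agg(dm), standard_scaled = agg(dstd))
}

#' Paired Wilcoxon signed-rank comparison of per-replicate metrics
#'
#' Non-parametric paired comparison of two goodness-of-normalization
#' metric vectors over synthetic replicates.  Zero differences are
#' discarded (classical signed-rank treatment); the exact distribution is
#' used for n <= 25 without ties, the normal approximation otherwise.
#' Significance stars follow the conventional thresholds: `*`, `**`,
#' `***` for p <= 0.05, 0.01, 0.001.
#'
#' @param a,b Paired numeric vectors (e.g. per-replicate rRMSE of two
#'   models).
#' @param alternative `"two.sided"`, `"less"` (a < b), or `"greater"`.
#'
#' @return A one-row tibble with `n_nonzero`, `statistic`, `p_value`,
#'   `stars`, and `degenerate` (`TRUE` when all differences are zero, in
#'   which case no test can be performed).
#' @examples
#' paired_compare(c(1, 2, 3, 4), c(2, 3, 4, 5), alternative = "less")
#' @export
paired_compare <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) abort("`a` and `b` must have the same length.")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(tibble::tibble(
      n_nonzero = 0L, statistic = NA_real_, p_value = NA_real_,
      stars = NA_character_, degenerate = TRUE
    ))
  }
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    wilcox.test(d, mu = 0, alternative = alternative, exact = exact)
  )
  tibble::tibble(
    n_nonzero = length(d),
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    stars = significance_stars(wt$p.value),
    degenerate = FALSE
  )
}

significance_stars <- function(p) {
  dplyr::case_when(
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
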