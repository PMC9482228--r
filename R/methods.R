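#' @export
print.volnorm_fit <- function(x, ...) {
  cat(sprintf(
    "<volnorm %s fit>  ell = %d, lambda = %.3g, loss = %s, transform = %s\n",
    toupper(x$model), x$ell, x$lambda, x$loss_kind, x$transform
  ))
  cat(sprintf(
    "  best of %d starts (start %d), objective = %.6g\n",
    x$n_starts, x$best_start, x$loss
  ))
  v <- x$volumes$volume
  cat(sprintf("  fitted volumes: %d time points, range [%.3g, %.3g]\n",
              length(v), min(v), max(v)))
  if (isTRUE(x$no_size_effect)) {
    cat("  NOTE: fitted volumes are constant - no size effect detected.\n")
  }
  invisible(x)
}

#' Tidy a fitted normalization model
#'
#' `tidy()` returns the fitted kinetic parameters (one row per metabolite
#' and parameter, with bounds and fixed flags); `glance()` returns a
#' one-row model summary; `augment()` returns the input data in long form
#' with fitted volumes and volume-normalized concentrations
#' \eqn{\hat C_j(t_i) = \tilde M_j(t_i) / \hat V(t_i)}.
#'
#' @param x,object A `volnorm_fit` from [fit_volumes()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.volnorm_fit <- function(x, ...) {
  x$kinetics
}

#' @rdname tidy.volnorm_fit
#' @export
glance.volnorm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    ell = x$ell,
    lambda = x$lambda,
    transform = x$transform,
    loss_kind = x$loss_kind,
    scaling = x$scaling,
    loss = x$loss,
    n_starts = x$n_starts,
    converged_starts = sum(is.finite(x$start_losses)),
    best_start = x$best_start,
    no_size_effect = x$no_size_effect,
    seed = x$seed
  )
}

#' @rdname tidy.volnorm_fit
#' @export
augment.volnorm_fit <- function(x, ...) {
  long <- tidyr::pivot_longer(
    x$data, -"time",
    names_to = "metabolite", values_to = "mass"
  )
  v <- x$volumes
  long <- dplyr::left_join(long, v, by = "time")
  long$concentration <- long$mass / long$volume
  long$modelled <- long$metabolite %in% x$modelled
  long
}

#' @rdname tidy.volnorm_fit
#' @export
autoplot.volnorm_fit <- function(object, ...) {
  v <- object$volumes
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$time, y = .data$volume)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = object$v_bounds, linetype = "dotted", colour = "grey50"
    ) +
    ggplot2::labs(
      x = "time (h)", y = "fitted volume",
      title = sprintf("%s fitted sample volumes", toupper(object$model))
    )
  if (!is.null(object$quotients)) {
    q <- object$quotients
    qs <- q * mean(v$volume) / mean(q) # overlay on the volume scale
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(time = v$time, volume = qs),
      ggplot2::aes(x = .data$time, y = .data$volume),
      colour = "steelblue", linetype = "dashed"
    )
  }
  p
}

#' @export
print.volnorm_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic dataset %s>  %d metabolites x %d time points, seed %d\n",
    x$version, ncol(x$concentrations), nrow(x$data), x$seed
  ))
  n_noise <- sum(x$noise_mask)
  if (n_noise > 0) cat(sprintf("  %d noise (volume-independent) metabolites\n", n_noise))
  invisible(x)
}

#' @rdname simulate_v1
#' @param object A `volnorm_dataset`.
#' @export
autoplot.volnorm_dataset <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$data, -"time",
    names_to = "metabolite", values_to = "mass"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time, y = .data$mass, group = .data$metabolite
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (h)", y = "measured mass (a.u.)",
      title = sprintf("Synthetic data (%s)", object$version)
    )
}
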