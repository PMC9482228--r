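# Shared validation for time x metabolite tables.  Returns a list with the
# time vector and the non-negative abundance matrix.  Exact zeros are
# legitimate (a metabolite not yet absorbed measures zero mass); negative or
# missing abundances are not.
check_mass_ts <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!"time" %in% names(data)) abort("`data` must contain a `time` column.")
  met_cols <- setdiff(names(data), "time")
  if (length(met_cols) < 1L) abort("`data` must contain at least one metabolite column.")
  m <- as.matrix(data[met_cols])
  if (!is.numeric(m)) abort("Metabolite columns must be numeric.")
  if (anyNA(m)) {
    abort("Missing abundance values are not supported; quotients are undefined.")
  }
  if (any(m < 0)) {
    abort("Abundances must be non-negative.")
  }
  if (anyDuplicated(data$time)) abort("Duplicate time stamps in `data`.")
  list(time = data$time, m = m, metabolites = met_cols)
}

#' Per-metabolite reference profile for PQN
#'
#' The reference abundance of metabolite \eqn{j} is the median of its
#' measured masses over all time points,
#' \eqn{M_j^{ref} = \mathrm{median}_i\, \tilde M_j(t_i)}.
#' Taking the median over the whole series (rather than a single dedicated
#' reference sample) damps the influence of experimental error on the
#' quotients.
#'
#' @param data A data frame with a `time` column and one non-negative
#'   numeric column per metabolite.  Missing values are rejected, and a
#'   metabolite whose reference median is zero makes the quotients
#'   undefined.
#' @param reference Reference type: `"median"` (metabolite-wise median over
#'   time points, the default), `"first"` (the first row, e.g. a dedicated
#'   reference sample), or a named numeric vector of custom reference
#'   abundances.
#'
#' @return A named numeric vector of reference abundances, one per
#'   metabolite column.
#' @examples
#' m <- tibble::tibble(time = 1:3, a = c(1, 2, 4), b = c(2, 4, 8))
#' reference_profile(m)
#' @export
reference_profile <- function(data, reference = c("median", "first")) {
  x <- check_mass_ts(data)
  if (is.numeric(reference)) {
    if (is.null(names(reference)) || !setequal(names(reference), x$metabolites)) {
      abort("A custom reference must be named after the metabolite columns.")
    }
    return(reference[x$metabolites])
  }
  reference <- match.arg(reference)
  switch(reference,
    median = apply(x$m, 2L, median),
    first = setNames(x$m[1L, ], x$metabolites)
  )
}

#' Probabilistic quotient normalization
#'
#' For each time point the PQN quotient is the median, over metabolites, of
#' the ratio of measured mass to the reference profile,
#' \eqn{Q^{PQN}(t) = \mathrm{median}_j\{\tilde M_j(t) / M_j^{ref}\}}.
#' Under the assumption that the median concentration fold change between
#' samples is ~1, the quotient is proportional to the sample volume:
#' \eqn{Q^{PQN}(t) = V(t) / V^{ref}} for an unknown, time-independent
#' reference volume.  PQN therefore recovers *relative* volume changes only.
#'
#' @inheritParams reference_profile
#'
#' @return A tibble of class `volnorm_pqn` with columns `time` and
#'   `quotient`, carrying the reference profile in the `reference`
#'   attribute.
#' @examples
#' m <- tibble::tibble(time = 1:3, a = c(1, 2, 4), b = c(2, 4, 8), c = c(3, 6, 12))
#' pqn_quotients(m)
#' @export
pqn_quotients <- function(data, reference = c("median", "first")) {
  x <- check_mass_ts(data)
  ref <- reference_profile(data, reference)
  if (any(ref <= 0)) {
    abort("Reference profile contains zero entries; quotients are undefined.")
  }
  ratios <- sweep(x$m, 2L, ref, "/")
  out <- tibble::tibble(
    time = x$time,
    quotient = apply(ratios, 1L, median)
  )
  attr(out, "reference") <- ref
  class(out) <- c("volnorm_pqn", class(out))
  out
}

#' @export
print.volnorm_pqn <- function(x, ...) {
  cat("PQN quotients over", nrow(x), "time points",
      sprintf("(%d metabolites in reference)\n", length(attr(x, "reference"))))
  NextMethod()
}

#' @rdname pqn_quotients
#' @param x A `volnorm_pqn` object.
#' @param object A `volnorm_pqn` object.
#' @param ... Unused.
#' @export
autoplot.volnorm_pqn <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$quotient)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "time (h)", y = expression(Q^PQN),
      title = "PQN quotients (relative sample volume)"
    )
}
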