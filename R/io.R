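#' Read and write mass time-series tables
#'
#' Plain-text tabular I/O for time x metabolite mass matrices: a `time`
#' column followed by one numeric column per metabolite.  TSV is used for
#' `.tsv`/`.txt` paths and CSV for `.csv`.  Reading validates the table
#' the same way the normalization functions do: numeric cells, no missing
#' values, no duplicated time stamps.
#'
#' @param path File path (`.tsv`, `.txt`, or `.csv`).
#' @param x A data frame with a `time` column and metabolite columns.
#'
#' @return `read_mass_matrix()` returns a tibble; `write_mass_matrix()`
#'   invisibly returns `path`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- tibble::tibble(time = 1:3, a = c(1, 2, 4))
#' write_mass_matrix(m, tf)
#' read_mass_matrix(tf)
#' @export
read_mass_matrix <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  out <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(out) == 0L) abort("Empty mass time series (header-only file).")
  if (!"time" %in% names(out)) abort("Mass matrix file must have a `time` column.")
  not_num <- names(out)[!vapply(out, is.numeric, logical(1))]
  if (length(not_num)) {
    abort(sprintf("Non-numeric cells in column(s): %s.", paste(not_num, collapse = ", ")))
  }
  if (anyNA(out)) abort("Missing values in mass matrix.")
  if (anyDuplicated(out$time)) abort("Duplicate time stamps in mass matrix.")
  out
}

#' @rdname read_mass_matrix
#' @export
write_mass_matrix <- function(x, path) {
  if (!"time" %in% names(x)) abort("`x` must have a `time` column.")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    readr::write_tsv(x, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a fitted model to plain-text files
#'
#' Writes the fitted volumes and kinetic parameter table of a
#' [fit_volumes()] result as TSV, plus a small JSON manifest carrying the
#' resolved hyperparameters and the seed needed to regenerate the fit.
#'
#' @param fit A `volnorm_fit`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir, prefix = fit$model) {
  if (!inherits(fit, "volnorm_fit")) abort("`fit` must be a volnorm_fit.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    volumes = file.path(dir, paste0(prefix, "_volumes.tsv")),
    kinetics = file.path(dir, paste0(prefix, "_kinetics.tsv")),
    manifest = file.path(dir, paste0(prefix, "_manifest.json"))
  )
  readr::write_tsv(fit$volumes, paths[["volumes"]], progress = FALSE)
  readr::write_tsv(fit$kinetics, paths[["kinetics"]], progress = FALSE)
  manifest <- glance(fit)
  jsonlite::write_json(as.list(manifest), paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
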