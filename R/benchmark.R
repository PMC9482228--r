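#' Define a benchmark grid
#'
#' Enumerates the experimental conditions of the synthetic benchmark: one
#' cell per combination of simulation version, number of metabolites, and
#' noise fraction, each evaluated with the requested normalization models
#' over a number of replicate data sets.
#'
#' @param versions Simulation versions, subset of `c("v1", "v2", "v3")`.
#' @param n_metabolites Numbers of metabolites (each >= 4).
#' @param noise_fractions Noise fractions in `[0, 0.95]`.
#' @param models Subset of `c("pqn", "pkm_minimal", "pkm_full",
#'   "mix_minimal", "mix_full")`.
#' @param replicates Synthetic replicates per cell (100 in the full
#'   benchmark).
#'
#' @return A tibble with one row per cell and a `cell` index.
#' @examples
#' benchmark_grid(versions = "v1", n_metabolites = 60, replicates = 5)
#' @export
benchmark_grid <- function(versions = "v1",
                           n_metabolites = c(4, 10, 20, 40, 60),
                           noise_fractions = 0,
                           models = c("pqn", "pkm_minimal", "mix_minimal"),
                           replicates = 100) {
  versions <- match.arg(versions, c("v1", "v2", "v3"), several.ok = TRUE)
  models <- match.arg(
    models,
    c("pqn", "pkm_minimal", "pkm_full", "mix_minimal", "mix_full"),
    several.ok = TRUE
  )
  grid <- tidyr::expand_grid(
    version = versions,
    n_metabolites = n_metabolites,
    noise_fraction = noise_fractions
  )
  grid$cell <- seq_len(nrow(grid))
  grid$models <- list(models)
  grid$replicates <- replicates
  grid
}

benchmark_model_names <- c("pqn", "pkm_minimal", "pkm_full", "mix_minimal", "mix_full")

#' Run the synthetic benchmark
#'
#' For every cell of a [benchmark_grid()]: generates the replicate data
#' sets, applies the noise fraction, fits the requested normalization
#' models, and collects RMSE and rRMSE against the known true volumes
#' (rRMSE only for PQN, which is scale-free).  Every data set and fit
#' seed is derived from the master seed by a counter scheme, so reruns
#' with the same seed reproduce the metric table exactly and all models
#' within a replicate see the same data (enabling paired comparisons).
#' Failures of individual fits are recorded in the `error` column and the
#' run continues.
#'
#' @param grid A [benchmark_grid()].
#' @param seed Master seed.
#' @param n_timepoints Time points per series.
#' @param cv Coefficient of variation of the multiplicative error.
#' @param n_starts Monte-Carlo starts per model fit.
#' @param out_dir If non-`NULL`, the metric table (TSV) and a JSON
#'   manifest (configuration, seed, config hash) are written there.
#' @param verbose Print per-cell progress to stderr.
#'
#' @return A tibble with one row per (cell, replicate, model):
#'   `version`, `n_metabolites`, `noise_fraction`, `model`, `replicate`,
#'   `rmse`, `rrmse`, `loss`, `seconds`, `error`.
#' @examples
#' g <- benchmark_grid(versions = "v1", n_metabolites = 6,
#'                     models = "pqn", replicates = 2)
#' run_benchmark(g, seed = 1)
#' @export
run_benchmark <- function(grid, seed = 1, n_timepoints = 20, cv = 0.2,
                          n_starts = 25, out_dir = NULL, verbose = FALSE) {
  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    models <- cell$models[[1]]
    if (verbose) {
      message(sprintf("cell %d/%d: %s n=%d f_n=%.2f",
                      ci, nrow(grid), cell$version, cell$n_metabolites,
                      cell$noise_fraction))
    }
    for (rep in seq_len(cell$replicates)) {
      rep_seed <- child_seed(seed, cell$cell, rep)
      ds <- switch(cell$version,
        v1 = simulate_v1(cell$n_metabolites, n_timepoints, cv, seed = rep_seed),
        v2 = simulate_v2(cell$n_metabolites, n_timepoints, cv, seed = rep_seed),
        v3 = simulate_v3(cell$n_metabolites, n_timepoints, cv, seed = rep_seed)
      )
      if (cell$noise_fraction > 0) ds <- apply_noise_fraction(ds, cell$noise_fraction)
      for (model in models) {
        res <- benchmark_one(ds, model, n_starts,
                             fit_seed = child_seed(seed, cell$cell, rep,
                                                   match(model, benchmark_model_names)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          version = cell$version,
          n_metabolites = cell$n_metabolites,
          noise_fraction = cell$noise_fraction,
          model = model,
          replicate = rep,
          rmse = res$rmse, rrmse = res$rrmse, loss = res$loss,
          seconds = res$seconds, error = res$error
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out, file.path(out_dir, "benchmark_metrics.tsv"), progress = FALSE)
    config <- list(
      grid = as.list(grid[setdiff(names(grid), "models")]),
      models = lapply(grid$models, identity),
      seed = seed, n_timepoints = n_timepoints, cv = cv, n_starts = n_starts
    )
    manifest <- list(
      config = config,
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("volnorm"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# Fit one model on one synthetic replicate and score it against the truth.
benchmark_one <- function(ds, model, n_starts, fit_seed) {
  v_true <- ds$volumes
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch({
    if (model == "pqn") {
      q <- pqn_quotients(ds$data)
      list(rmse = NA_real_, rrmse = rrmse_volumes(v_true, q$quotient),
           loss = NA_real_, error = NA_character_)
    } else {
      n_mets <- ncol(ds$concentrations)
      ell <- if (grepl("minimal", model)) min(ds$n_targeted, n_mets) else n_mets
      mets <- colnames(ds$concentrations)[seq_len(ell)]
      spec <- model_spec(
        ell = ell,
        params = toy_parameter_table(mets),
        n_starts = n_starts
      )
      kind <- if (grepl("pkm", model)) "pkm" else "mix"
      fit <- suppressWarnings(
        fit_volumes(ds$data, spec, model = kind, seed = fit_seed)
      )
      v_fit <- fit$volumes$volume
      list(rmse = rmse_volumes(v_true, v_fit),
           rrmse = rrmse_volumes(v_true, v_fit),
           loss = fit$loss, error = NA_character_)
    }
  }, error = function(e) {
    list(rmse = NA_real_, rrmse = NA_real_, loss = NA_real_,
         error = conditionMessage(e))
  })
  out$seconds <- proc.time()[["elapsed"]] - t0
  out
}
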