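#' Filter an LC-MS alignment feature table
#'
#' Applies the three pre-filtering rules used on exported alignment tables
#' before normalization, per time series:
#'
#' 1. **Retention-time rule** -- features eluting after `rt_max` minutes
#'    are removed (late eluters are likely background).
#' 2. **Blank rule** -- features whose *minimum* sample abundance is below
#'    `blank_factor` times the *maximum* blank abundance are removed,
#'    except spike-in / internal-standard features (which are also present
#'    in blanks by design).
#' 3. **Isomer rule** -- among the survivors, features closer than
#'    `isomer_dm` in m/z *and* `isomer_drt` in retention time are
#'    de-duplicated; the member with the higher maximum sample abundance
#'    (the better-quantified peak) is kept.
#'
#' The RT and blank rules are independent set filters; the isomer rule is
#' applied last on their survivors.  Filtering is idempotent.
#'
#' @param features Data frame with columns `feature_id`, `mz` (Da), `rt`
#'   (min), plus per-sample abundance columns.
#' @param sample_cols Character vector naming the sample abundance
#'   columns.
#' @param blank_cols Character vector naming the blank abundance columns;
#'   defaults to columns whose name contains "blank".
#' @param rt_max Retention-time cutoff (min).
#' @param blank_factor Multiple of the maximum blank abundance a feature's
#'   minimum sample abundance must reach; `NULL` disables the blank rule.
#' @param isomer_dm,isomer_drt Isomer windows: m/z difference (Da) and RT
#'   difference (min) below which two features count as the same compound.
#' @param spike_in_ids Feature ids exempt from the blank rule.
#'
#' @return The filtered tibble, with a `removed` attribute logging
#'   `feature_id` and the rule that removed each dropped feature.
#' @examples
#' ft <- tibble::tibble(
#'   feature_id = c("a", "b"), mz = c(100.1, 200.2), rt = c(1.2, 5.9),
#'   s1 = c(1000, 800), s2 = c(1200, 900), blank1 = c(10, 10)
#' )
#' filter_features(ft, sample_cols = c("s1", "s2"))
#' @export
filter_features <- function(features,
                            sample_cols,
                            blank_cols = grep("blank", names(features),
                                              ignore.case = TRUE, value = TRUE),
                            rt_max = 5.5,
                            blank_factor = 5,
                            isomer_dm = 0.001,
                            isomer_drt = 0.5,
                            spike_in_ids = NULL) {
  needed <- c("feature_id", "mz", "rt")
  if (!all(needed %in% names(features))) {
    abort("`features` needs columns feature_id, mz, rt.")
  }
  if (nrow(features) == 0L) {
    out <- tibble::as_tibble(features)
    attr(out, "removed") <- tibble::tibble(feature_id = character(), rule = character())
    return(out)
  }
  if (any(features$mz <= 0) || any(features$rt < 0)) {
    abort("m/z must be positive and retention times non-negative.")
  }
  missing_cols <- setdiff(sample_cols, names(features))
  if (length(missing_cols)) abort("Unknown sample columns.")
  removed <- list()

  keep_rt <- features$rt <= rt_max
  removed$rt <- features$feature_id[!keep_rt]

  keep_blank <- rep(TRUE, nrow(features))
  if (!is.null(blank_factor)) {
    if (length(blank_cols) == 0L) {
      abort("Blank rule requested but no blank columns found.")
    }
    smin <- apply(as.matrix(features[sample_cols]), 1L, min)
    bmax <- apply(as.matrix(features[blank_cols]), 1L, max)
    keep_blank <- smin >= blank_factor * bmax |
      features$feature_id %in% spike_in_ids
    removed$blank <- features$feature_id[!keep_blank]
  }

  surv <- features[keep_rt & keep_blank, , drop = FALSE]

  # isomer de-duplication: greedy by maximum sample abundance, so the
  # better-quantified member of each close pair is kept
  if (nrow(surv) > 1L) {
    amax <- apply(as.matrix(surv[sample_cols]), 1L, max)
    ord <- order(-amax)
    kept_idx <- integer(0)
    drop_ids <- character(0)
    for (i in ord) {
      clash <- any(
        abs(surv$mz[kept_idx] - surv$mz[i]) < isomer_dm &
          abs(surv$rt[kept_idx] - surv$rt[i]) < isomer_drt
      )
      if (clash) {
        drop_ids <- c(drop_ids, surv$feature_id[i])
      } else {
        kept_idx <- c(kept_idx, i)
      }
    }
    removed$isomer <- drop_ids
    surv <- surv[sort(kept_idx), , drop = FALSE]
  }

  out <- tibble::as_tibble(surv)
  attr(out, "removed") <- dplyr::bind_rows(lapply(names(removed), function(rule) {
    tibble::tibble(feature_id = removed[[rule]], rule = rule)
  }))
  out
}
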