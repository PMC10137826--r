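#' Replace missing values by the cohort's detection-limit sentinel
#'
#' Missing entries in circulating-miRNA profiles denote measurements below
#' the platform's detection limit, not missing-at-random data. They are
#' replaced by the global minimum of all observed values in the cohort's
#' matrix. For Ct-scale cohorts the sentinel is the global *maximum* instead,
#' because an undetected transcript has the highest cycle threshold.
#'
#' @param cohort A `mir_cohort`, possibly containing `NA` entries.
#' @return The cohort with every missing entry replaced; no other value is
#'   changed.
#' @export
impute_missing <- function(cohort) {
  stopifnot(inherits(cohort, "mir_cohort"))
  v <- cohort$values
  if (all(is.na(v))) stop("all values missing; nothing to impute from", call. = FALSE)
  if (anyNA(v)) {
    sentinel <- if (cohort$scale == "ct") max(v, na.rm = TRUE) else min(v, na.rm = TRUE)
    v[is.na(v)] <- sentinel
    cohort$values <- v
  }
  cohort
}

#' Exclude low-abundance miRNAs pinned at the detection limit
#'
#' A miRNA is removed when, in the healthy group *or* in the COPD group, the
#' fraction of samples whose value sits at the cohort-wide detection-limit
#' sentinel (the matrix minimum, or maximum for Ct-scale cohorts) is strictly
#' greater than `threshold`. Such features carry no ordering information in
#' the group where they are pinned. Equality with the sentinel is tested up
#' to a 1e-12 relative tolerance so that serialization round-trips do not
#' change the outcome; imputed entries are bit-identical to the sentinel.
#'
#' @param cohort An imputed `mir_cohort` (no missing values).
#' @param threshold Fraction in (0, 1]; removal requires the pinned
#'   proportion to strictly exceed it. Default 0.7.
#' @return The filtered `mir_cohort`, with the removal report attached
#'   (retrieve with [filter_report()]).
#' @export
filter_low_abundance <- function(cohort, threshold = 0.7) {
  stopifnot(inherits(cohort, "mir_cohort"))
  if (anyNA(cohort$values)) {
    stop("cohort contains missing values; run impute_missing() first",
         call. = FALSE)
  }
  stopifnot(threshold > 0, threshold <= 1)
  for (cl in .mirpair_classes) {
    if (sum(cohort$labels == cl) == 0) {
      stop("group '", cl, "' has zero samples", call. = FALSE)
    }
  }
  v <- cohort$values
  sentinel <- if (cohort$scale == "ct") max(v) else min(v)
  at_sent <- abs(v - sentinel) <= 1e-12 * max(abs(sentinel), 1)

  props <- lapply(.mirpair_classes, function(cl) {
    rowMeans(at_sent[, cohort$labels == cl, drop = FALSE])
  })
  names(props) <- .mirpair_classes

  report <- purrr::map_dfr(.mirpair_classes, function(cl) {
    p <- props[[cl]]
    tibble::tibble(feature = names(p)[p > threshold],
                   group = cl,
                   prop_min = unname(p[p > threshold]))
  })
  drop <- unique(report$feature)
  n_before <- nrow(v)
  cohort$values <- v[setdiff(rownames(v), drop), , drop = FALSE]
  attr(report, "threshold") <- threshold
  attr(report, "n_before") <- n_before
  attr(report, "n_after") <- nrow(cohort$values)
  attr(cohort, "filter_report") <- report
  cohort
}

#' Retrieve the removal report from a filtered cohort
#'
#' @param cohort A cohort returned by [filter_low_abundance()].
#' @return A tibble with columns `feature`, `group`, `prop_min` and
#'   attributes `threshold`, `n_before`, `n_after`.
#' @export
filter_report <- function(cohort) {
  rep <- attr(cohort, "filter_report")
  if (is.null(rep)) stop("cohort has no filter report; run filter_low_abundance()",
                         call. = FALSE)
  rep
}
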