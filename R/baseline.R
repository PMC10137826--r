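#' Per-miRNA differential expression (expression-level baseline)
#'
#' The expression-level baseline the pair method is compared against: a
#' Welch two-sample t-test per feature on the cohort's working scale, with
#' logFC as the COPD-minus-healthy mean difference. The working scale is
#' assumed log2-like for expression cohorts; Ct-scale cohorts are negated
#' first (higher Ct = lower expression). Stringent mode flags
#' `|logFC| > logfc_thresh` and `p < p_thresh`; relaxed mode uses the p
#' threshold only. BH-adjusted p-values are reported, but flagging uses the
#' raw p-value. A feature with zero variance and equal group means gets
#' p = 1 by convention.
#'
#' Unlike pair scores, these flags are *not* invariant to per-platform
#' monotone distortions — the instability that motivates the pair transform.
#'
#' @param cohort A preprocessed `mir_cohort` with >= 2 samples per class.
#' @param logfc_thresh Absolute logFC threshold (stringent mode), default 1.5.
#' @param p_thresh Raw p-value threshold, default 0.05.
#' @param stringent If `TRUE` apply both thresholds; if `FALSE` only p.
#' @return A tibble of class `mir_de` with columns `feature`, `logfc`,
#'   `p_value`, `adj_p`, `direction`, `flagged`.
#' @export
differential_expression <- function(cohort, logfc_thresh = 1.5,
                                    p_thresh = 0.05, stringent = TRUE) {
  stopifnot(inherits(cohort, "mir_cohort"))
  if (anyNA(cohort$values)) {
    stop("cohort contains missing values; run impute_missing() first", call. = FALSE)
  }
  labels <- cohort$labels
  if (min(table(labels)) < 2) stop("need >= 2 samples per class", call. = FALSE)
  v <- cohort$values
  if (cohort$scale == "ct") v <- -v
  copd <- labels == "COPD"

  res <- purrr::map_dfr(rownames(v), function(f) {
    x <- v[f, copd]
    y <- v[f, !copd]
    lfc <- mean(x) - mean(y)
    p <- tryCatch(t.test(x, y)$p.value,        # Welch by default
                  error = function(e) 1)       # degenerate: constant data
    if (is.na(p)) p <- 1
    tibble::tibble(feature = f, logfc = lfc, p_value = p)
  })
  res$adj_p <- p.adjust(res$p_value, method = "BH")
  res$direction <- ifelse(res$logfc >= 0, "up", "down")
  res$flagged <- if (stringent) {
    abs(res$logfc) > logfc_thresh & res$p_value < p_thresh
  } else {
    res$p_value < p_thresh
  }
  attr(res, "thresholds") <- list(logfc = logfc_thresh, p = p_thresh,
                                  stringent = stringent)
  class(res) <- c("mir_de", class(res))
  res
}

#' ROC performance of a single miRNA's expression level
#'
#' Direction-corrected AUC of one feature's continuous values for COPD vs
#' healthy, with a DeLong 95% CI. Ct-scale cohorts are negated first so the
#' score is always on an expression-like scale; if the feature discriminates
#' in the "down in COPD" direction the sign is flipped before the CI is
#' computed (direction correction).
#'
#' @param cohort A preprocessed `mir_cohort`.
#' @param feature A feature name present in the cohort.
#' @return A one-row tibble with `feature`, `auc`, `ci_low`, `ci_high`,
#'   `direction` (`up`/`down` in COPD).
#' @export
single_mirna_auc <- function(cohort, feature) {
  stopifnot(inherits(cohort, "mir_cohort"))
  if (!feature %in% rownames(cohort$values)) {
    stop("feature not in cohort: ", feature, call. = FALSE)
  }
  x <- cohort$values[feature, ]
  if (anyNA(x)) stop("feature has missing values; impute first", call. = FALSE)
  if (cohort$scale == "ct") x <- -x
  raw <- rank_auc(x, cohort$labels == "COPD")
  direction <- if (raw >= 0.5) "up" else "down"
  if (raw < 0.5) x <- -x
  out <- roc_auc_ci(x, cohort$labels)
  dplyr::bind_cols(tibble::tibble(feature = feature), out,
                   tibble::tibble(direction = direction))
}
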