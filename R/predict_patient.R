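#' Predict COPD status for a single patient
#'
#' Single-patient front end to a fitted pair model. Input is either the
#' patient's pair scores directly (0 when miRNA-A is expressed less than
#' miRNA-B in the `"miRNA-A|miRNA-B"` pair, otherwise 1), or raw per-miRNA
#' measurements, which are converted to pair scores with [pair_score()].
#' For Ct input, "expression of A less than B" means `Ct_A > Ct_B`; this
#' inversion is on by default and can be disabled with `ct_invert = FALSE`
#' for pipelines whose Ct values were already negated upstream.
#'
#' @param model A `mir_model`.
#' @param pair_scores Named 0/1 vector covering the model's pair schema
#'   (names are `"a|b"` identifiers). Mutually exclusive with `values`.
#' @param values Named numeric vector of per-miRNA measurements covering
#'   every miRNA in the schema's pairs.
#' @param scale Scale of `values`: `"expression"` or `"ct"`.
#' @param ct_invert Whether Ct values imply inverted comparisons (default
#'   `TRUE`; ignored for expression input).
#' @param sample_id Identifier echoed in the output.
#' @return A one-row tibble: `sample`, `predicted_class`, `p_copd`,
#'   `algorithm`, plus the derived pair scores as attribute
#'   `"pair_scores"`.
#' @export
predict_patient <- function(model, pair_scores = NULL, values = NULL,
                            scale = c("expression", "ct"), ct_invert = TRUE,
                            sample_id = "patient") {
  stopifnot(inherits(model, "mir_model"))
  scale <- check_scale(scale)
  if (is.null(pair_scores) == is.null(values)) {
    stop("supply exactly one of `pair_scores` or `values`", call. = FALSE)
  }
  schema <- model$feature_schema

  if (!is.null(values)) {
    if (is.null(names(values))) stop("`values` must be named by miRNA", call. = FALSE)
    members <- pair_members(schema)
    needed <- unique(c(members$a, members$b))
    gaps <- setdiff(needed, names(values))
    if (length(gaps) > 0) {
      stop("missing value(s) for miRNA(s): ", paste(gaps, collapse = ", "),
           call. = FALSE)
    }
    extras <- setdiff(names(values), needed)
    if (length(extras) > 0) {
      warning("ignoring out-of-schema miRNA(s): ",
              paste(extras, collapse = ", "), call. = FALSE)
    }
    eff_scale <- if (scale == "ct" && !ct_invert) "expression" else scale
    pair_scores <- setNames(
      pair_score(values[members$a], values[members$b], scale = eff_scale),
      schema
    )
  } else {
    if (is.null(names(pair_scores))) {
      stop("`pair_scores` must be named by pair id", call. = FALSE)
    }
    gaps <- setdiff(schema, names(pair_scores))
    if (length(gaps) > 0) {
      stop("missing pair score(s): ", paste(gaps, collapse = ", "), call. = FALSE)
    }
    extras <- setdiff(names(pair_scores), schema)
    if (length(extras) > 0) {
      warning("ignoring out-of-schema pair(s): ",
              paste(extras, collapse = ", "), call. = FALSE)
    }
    if (!all(pair_scores %in% c(0, 1))) {
      stop("pair scores must be 0 or 1", call. = FALSE)
    }
  }

  X <- matrix(as.numeric(pair_scores[schema]), nrow = 1,
              dimnames = list(sample_id, schema))
  pred <- predict(model, X)
  out <- tibble::tibble(sample = sample_id,
                        predicted_class = pred$predicted_class,
                        p_copd = pred$p_copd,
                        algorithm = model$algorithm)
  attr(out, "pair_scores") <- pair_scores[schema]
  out
}
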