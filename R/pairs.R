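#' Score a miRNA pair from two abundance values
#'
#' The pair score encodes only the within-sample ordering of two miRNAs: it
#' is 0 when miRNA-A is expressed less than miRNA-B, and 1 otherwise (ties
#' score 1). On the Ct scale the comparison is inverted, since a lower cycle
#' threshold means higher expression; the returned score therefore always has
#' expression-scale semantics regardless of the input platform.
#'
#' @param value_a,value_b Abundance values (vectorized).
#' @param scale `"expression"` (larger = more abundant) or `"ct"`
#'   (larger = less abundant).
#' @return Integer vector of 0/1 scores.
#' @export
pair_score <- function(value_a, value_b, scale = c("expression", "ct")) {
  scale <- check_scale(scale)
  if (anyNA(value_a) || anyNA(value_b)) {
    stop("pair_score requires non-missing values; impute first", call. = FALSE)
  }
  if (scale == "ct") {
    as.integer(value_a <= value_b)  # lower Ct = higher expression
  } else {
    as.integer(value_a >= value_b)
  }
}

#' Enumerate all unordered miRNA pairs
#'
#' Returns every unordered pair of the given features as `"a|b"` identifiers
#' in canonical orientation (`a` before `b` lexicographically), in a
#' deterministic order: features are sorted, then pairs enumerated
#' first-by-first member.
#'
#' @param features Character vector of >= 2 feature names.
#' @return Character vector of `n*(n-1)/2` pair identifiers.
#' @export
enumerate_pairs <- function(features) {
  features <- as.character(features)
  if (length(features) < 2) stop("need >= 2 features to form pairs", call. = FALSE)
  if (anyDuplicated(features)) stop("duplicate feature names", call. = FALSE)
  f <- sort(features)
  cmb <- combn(f, 2L)
  paste(cmb[1L, ], cmb[2L, ], sep = "|")
}

#' Split pair identifiers into their member miRNAs
#'
#' @param pairs Character vector of `"a|b"` identifiers.
#' @return A tibble with columns `pair`, `a`, `b`.
#' @export
pair_members <- function(pairs) {
  parts <- strsplit(pairs, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed pair id(s): ", paste(pairs[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(pair = pairs,
                 a = vapply(parts, `[`, character(1), 1L),
                 b = vapply(parts, `[`, character(1), 2L))
}

#' Transform an expression cohort into a binary pair matrix
#'
#' Every requested pair `a|b` is scored in every sample with [pair_score()],
#' producing a 0/1 pair-by-sample matrix. Because only orderings enter, the
#' result is invariant to any strictly increasing transform of the whole
#' input matrix — the property that makes pair features comparable across
#' platforms.
#'
#' @param cohort A preprocessed `mir_cohort` (no missing values).
#' @param pairs `"all"` (default: all unordered pairs of the cohort's
#'   features) or a character vector of `"a|b"` identifiers.
#' @return An object of class `mir_pairs` with elements `scores`
#'   (integer pair x sample matrix), `labels`, and `pairs`.
#' @export
build_pair_matrix <- function(cohort, pairs = "all") {
  stopifnot(inherits(cohort, "mir_cohort"))
  if (anyNA(cohort$values)) {
    stop("cohort contains missing values; run impute_missing() first", call. = FALSE)
  }
  if (identical(pairs, "all")) {
    pairs <- enumerate_pairs(rownames(cohort$values))
  }
  if (anyDuplicated(pairs)) stop("duplicate pair identifiers", call. = FALSE)
  pm <- pair_members(pairs)
  missing_feats <- setdiff(unique(c(pm$a, pm$b)), rownames(cohort$values))
  if (length(missing_feats) > 0) {
    stop("pair(s) reference miRNA(s) absent from the cohort: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  A <- cohort$values[pm$a, , drop = FALSE]
  B <- cohort$values[pm$b, , drop = FALSE]
  scores <- if (cohort$scale == "ct") (A <= B) else (A >= B)
  storage.mode(scores) <- "integer"
  rownames(scores) <- pairs
  new_pair_matrix(scores, cohort$labels)
}

new_pair_matrix <- function(scores, labels) {
  stopifnot(is.matrix(scores), all(scores %in% c(0L, 1L)))
  labels <- as_class_factor(labels)
  names(labels) <- colnames(scores)
  structure(list(scores = scores, labels = labels, pairs = rownames(scores)),
            class = "mir_pairs")
}

#' @export
print.mir_pairs <- function(x, ...) {
  cat("<mir_pairs> ", nrow(x$scores), " pairs x ", ncol(x$scores), " samples (",
      sum(x$labels == "COPD"), " COPD / ", sum(x$labels == "healthy"),
      " healthy)\n", sep = "")
  invisible(x)
}

#' @rdname build_pair_matrix
#' @param x A `mir_pairs` object.
#' @param ... Unused.
#' @export
tidy.mir_pairs <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "pair") |>
    tidyr::pivot_longer(-"pair", names_to = "sample", values_to = "score") |>
    dplyr::mutate(label = as.character(x$labels[.data$sample]))
}

#' Merge pair matrices from independent cohorts
#'
#' Because pair scores have the same 0/1 semantics on every platform, cohorts
#' become directly comparable after the pair transform. Merging concatenates
#' samples and restricts to pairs present in every input, in canonical order.
#'
#' @param pair_matrices List of `mir_pairs` objects with disjoint sample IDs.
#' @return A single merged `mir_pairs`.
#' @export
merge_pair_matrices <- function(pair_matrices) {
  stopifnot(is.list(pair_matrices), length(pair_matrices) >= 2)
  for (pm in pair_matrices) stopifnot(inherits(pm, "mir_pairs"))
  all_samples <- unlist(lapply(pair_matrices, function(pm) colnames(pm$scores)))
  dup <- unique(all_samples[duplicated(all_samples)])
  if (length(dup) > 0) {
    stop("duplicate sample ID(s) across cohorts: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  common <- Reduce(intersect, lapply(pair_matrices, function(pm) pm$pairs))
  if (length(common) == 0) stop("no pairs shared by all cohorts", call. = FALSE)
  common <- sort(common)
  scores <- do.call(cbind, lapply(pair_matrices,
                                  function(pm) pm$scores[common, , drop = FALSE]))
  labels <- unlist(lapply(pair_matrices,
                          function(pm) as.character(pm$labels)), use.names = FALSE)
  names(labels) <- all_samples
  new_pair_matrix(scores, labels)
}

#' Drop pairs with identical scores in every sample
#'
#' Zero-variance pairs cannot discriminate anything; dropping them shrinks
#' the feature space. Off by default in the pipeline — enumeration is the
#' contract, variance filtering an explicit opt-in.
#'
#' @param pair_matrix A `mir_pairs`.
#' @return The `mir_pairs` restricted to pairs with both scores observed.
#' @export
drop_zero_variance_pairs <- function(pair_matrix) {
  stopifnot(inherits(pair_matrix, "mir_pairs"))
  keep <- rowSums(pair_matrix$scores) %% ncol(pair_matrix$scores) != 0
  new_pair_matrix(pair_matrix$scores[keep, , drop = FALSE], pair_matrix$labels)
}

#' Write / read a pair matrix as CSV
#'
#' Rows are `"a|b"` identifiers, columns sample IDs, cells 0/1; labels go to
#' a companion two-column file.
#'
#' @param pair_matrix A `mir_pairs`.
#' @param matrix_path,labels_path File paths.
#' @return `write_pair_matrix()`: the input, invisibly.
#'   `read_pair_matrix()`: a `mir_pairs`.
#' @export
write_pair_matrix <- function(pair_matrix, matrix_path, labels_path) {
  stopifnot(inherits(pair_matrix, "mir_pairs"))
  readr::write_csv(tibble::as_tibble(pair_matrix$scores, rownames = "pair"),
                   matrix_path)
  readr::write_csv(
    tibble::tibble(sample_id = names(pair_matrix$labels),
                   class = as.character(pair_matrix$labels)),
    labels_path
  )
  invisible(pair_matrix)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(matrix_path, labels_path) {
  df <- read_delimited(matrix_path)
  scores <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(scores) <- "integer"
  rownames(scores) <- as.character(df[[1]])
  lab_df <- read_delimited(labels_path)
  labels <- setNames(as.character(lab_df[[2]]), as.character(lab_df[[1]]))
  missing_lab <- setdiff(colnames(scores), names(labels))
  if (length(missing_lab) > 0) {
    stop("no label for sample(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  }
  new_pair_matrix(scores, labels[colnames(scores)])
}
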