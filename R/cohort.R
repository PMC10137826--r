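#' Construct an expression cohort
#'
#' An expression cohort bundles a miRNA-by-sample abundance matrix with
#' per-sample class labels and a value-scale flag. On the `"expression"`
#' scale larger values mean more abundant (microarray intensities, normalized
#' counts, log-expression); on the `"ct"` scale larger values mean *less*
#' abundant (qPCR cycle thresholds). Abundance units are platform-specific
#' and are never compared across cohorts — only within-sample orderings are
#' used downstream.
#'
#' @param values Numeric matrix, features in rows (rownames = miRNA names),
#'   samples in columns (colnames = sample IDs). `NA` entries are permitted
#'   before preprocessing and denote below-detection measurements.
#' @param labels Class label per sample, `"COPD"` or `"healthy"`. Either an
#'   unnamed vector in column order or a vector named by sample ID.
#' @param scale `"expression"` or `"ct"`.
#' @param cohort_id Short identifier used in reports.
#'
#' @return An object of class `mir_cohort`.
#' @export
expression_cohort <- function(values, labels, scale = c("expression", "ct"),
                              cohort_id = "cohort") {
  scale <- check_scale(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (miRNAs) and colnames (sample IDs)",
         call. = FALSE)
  }
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup) > 0) {
    stop("duplicate feature name(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs in matrix", call. = FALSE)
  }
  if (!is.null(names(labels))) {
    missing_lab <- setdiff(colnames(values), names(labels))
    if (length(missing_lab) > 0) {
      stop("no label for sample(s): ", paste(missing_lab, collapse = ", "),
           call. = FALSE)
    }
    labels <- labels[colnames(values)]
  } else if (length(labels) != ncol(values)) {
    stop("`labels` length (", length(labels), ") does not match sample count (",
         ncol(values), ")", call. = FALSE)
  }
  labels <- as_class_factor(labels)
  names(labels) <- colnames(values)
  structure(
    list(cohort_id = cohort_id, values = values, labels = labels, scale = scale),
    class = "mir_cohort"
  )
}

#' @export
print.mir_cohort <- function(x, ...) {
  cat("<mir_cohort> ", x$cohort_id, "\n", sep = "")
  cat("  ", nrow(x$values), " miRNAs x ", ncol(x$values), " samples (",
      sum(x$labels == "COPD"), " COPD / ", sum(x$labels == "healthy"),
      " healthy)\n", sep = "")
  cat("  scale: ", x$scale, "; missing entries: ", sum(is.na(x$values)),
      "\n", sep = "")
  invisible(x)
}

#' @rdname expression_cohort
#' @param x A `mir_cohort`.
#' @param ... Unused.
#' @export
tidy.mir_cohort <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "sample", values_to = "value") |>
    dplyr::mutate(label = as.character(x$labels[.data$sample]))
}

#' @rdname expression_cohort
#' @export
glance.mir_cohort <- function(x, ...) {
  tibble::tibble(
    cohort_id = x$cohort_id,
    n_features = nrow(x$values),
    n_samples = ncol(x$values),
    n_copd = sum(x$labels == "COPD"),
    n_healthy = sum(x$labels == "healthy"),
    n_missing = sum(is.na(x$values)),
    scale = x$scale
  )
}

#' Read an expression cohort from delimited text
#'
#' The matrix file has miRNA names in the first column and sample IDs in the
#' header row; empty cells are parsed as missing. The labels file has two
#' columns, sample ID and class (`COPD`/`healthy`), with or without a header.
#' Comma and tab delimiters are auto-detected from the file contents.
#'
#' @param matrix_path Path to the expression matrix (CSV/TSV).
#' @param labels_path Path to the two-column label table (CSV/TSV).
#' @inheritParams expression_cohort
#' @return A [expression_cohort()] object.
#' @export
read_cohort <- function(matrix_path, labels_path, scale = c("expression", "ct"),
                        cohort_id = NULL) {
  scale <- check_scale(scale)
  if (is.null(cohort_id)) {
    cohort_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  }
  mat_df <- read_delimited(matrix_path)
  if (ncol(mat_df) < 2) stop("matrix file needs >= 1 sample column", call. = FALSE)
  feats <- as.character(mat_df[[1]])
  dup <- unique(feats[duplicated(feats)])
  if (length(dup) > 0) {
    stop("duplicate feature name(s) in ", matrix_path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- feats

  lab_df <- read_delimited(labels_path)
  # tolerate headerless files: first row may already be data
  if (ncol(lab_df) < 2) stop("labels file needs two columns", call. = FALSE)
  lab <- setNames(as.character(lab_df[[2]]), as.character(lab_df[[1]]))
  expression_cohort(values, lab, scale = scale, cohort_id = cohort_id)
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, name_repair = "minimal")
}

#' Write an expression cohort to delimited text
#'
#' Inverse of [read_cohort()]: round-tripping reproduces the matrix up to
#' floating-point formatting.
#'
#' @param cohort A `mir_cohort`.
#' @param matrix_path,labels_path Output paths (CSV).
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, matrix_path, labels_path) {
  stopifnot(inherits(cohort, "mir_cohort"))
  df <- tibble::as_tibble(cohort$values, rownames = "miRNA")
  readr::write_csv(df, matrix_path, na = "")
  readr::write_csv(
    tibble::tibble(sample_id = names(cohort$labels),
                   class = as.character(cohort$labels)),
    labels_path
  )
  invisible(cohort)
}

#' Read a miRNA alias mapping table
#'
#' Two delimited columns: `source_name`, `canonical_name`. Used to re-annotate
#' platform-specific probe names to a common nomenclature (e.g. current
#' miRBase names) before intersecting cohorts. Many-to-one maps are allowed;
#' collisions within a cohort are an error at [harmonize_names()] time.
#'
#' @param path Path to a two-column CSV/TSV.
#' @return A tibble with columns `source_name`, `canonical_name`.
#' @export
read_alias_map <- function(path) {
  df <- read_delimited(path)
  if (ncol(df) < 2) stop("alias map needs two columns", call. = FALSE)
  out <- tibble::tibble(source_name = as.character(df[[1]]),
                        canonical_name = as.character(df[[2]]))
  dup <- out$source_name[duplicated(out$source_name)]
  if (length(dup) > 0) {
    bad <- out |>
      dplyr::filter(.data$source_name %in% dup) |>
      dplyr::distinct() |>
      dplyr::count(.data$source_name) |>
      dplyr::filter(.data$n > 1)
    if (nrow(bad) > 0) {
      stop("source name(s) mapped to multiple canonical names: ",
           paste(bad$source_name, collapse = ", "), call. = FALSE)
    }
    out <- dplyr::distinct(out)
  }
  out
}

#' Harmonize miRNA names via an alias map
#'
#' Renames features to their canonical names; features absent from the map
#' pass through unchanged. Matrix values are never modified. If two source
#' features would collapse onto the same canonical name the call errors —
#' probe merging is a curation decision the caller must make explicitly.
#'
#' @param cohort A `mir_cohort`.
#' @param alias_map Data frame with columns `source_name`, `canonical_name`
#'   (see [read_alias_map()]).
#' @return The renamed `mir_cohort`.
#' @export
harmonize_names <- function(cohort, alias_map) {
  stopifnot(inherits(cohort, "mir_cohort"))
  if (nrow(alias_map) == 0) return(cohort)
  map <- setNames(as.character(alias_map$canonical_name),
                  as.character(alias_map$source_name))
  old <- rownames(cohort$values)
  new <- ifelse(old %in% names(map), unname(map[old]), old)
  dup <- unique(new[duplicated(new)])
  if (length(dup) > 0) {
    collided <- vapply(dup, function(d) {
      paste0(d, " <- {", paste(old[new == d], collapse = ", "), "}")
    }, character(1))
    stop("harmonization collapses distinct features onto one name:\n  ",
         paste(collided, collapse = "\n  "), call. = FALSE)
  }
  rownames(cohort$values) <- new
  cohort
}

#' Restrict cohorts to their common feature set
#'
#' Cross-platform analysis only uses miRNAs measured in every cohort. Each
#' returned cohort is restricted to the shared features in lexicographic
#' order, so all outputs have identical row order.
#'
#' @param cohorts A list of `mir_cohort` objects (>= 2) with harmonized names.
#' @return A list of `mir_cohort` objects over the sorted common feature set.
#' @export
intersect_features <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2)
  for (co in cohorts) stopifnot(inherits(co, "mir_cohort"))
  common <- Reduce(intersect, lapply(cohorts, function(co) rownames(co$values)))
  if (length(common) == 0) {
    stop("cohorts share no features after harmonization", call. = FALSE)
  }
  common <- sort(common)
  lapply(cohorts, function(co) {
    co$values <- co$values[common, , drop = FALSE]
    co
  })
}
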