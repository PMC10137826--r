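#' AUC of a binary pair feature
#'
#' Computes the ROC area of a 0/1 feature as a predictor of COPD using the
#' tie-aware rank (Mann-Whitney) statistic. For a binary predictor this
#' reduces to `(TPR + TNR) / 2` with `TPR = P(score = 1 | COPD)` and
#' `TNR = P(score = 0 | healthy)`. The direction-corrected value
#' `max(AUC, 1 - AUC)` is reported alongside, so that an informative pair is
#' not lost to its (arbitrary) canonical orientation.
#'
#' @param scores Numeric vector of 0/1 scores over samples.
#' @param labels Class vector (`"COPD"`/`"healthy"`), COPD positive.
#' @return A one-row tibble with columns `auc` and `auc_corrected`.
#' @export
binary_feature_auc <- function(scores, labels) {
  labels <- as_class_factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  auc <- rank_auc(scores, labels == "COPD")
  tibble::tibble(auc = auc, auc_corrected = max(auc, 1 - auc))
}

# Tie-corrected rank AUC; `pos` logical. Equals Mann-Whitney U / (n1*n0).
rank_auc <- function(scores, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)  # average ranks under ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Vectorized over the rows of a 0/1 matrix: per-row raw AUC.
matrix_binary_auc <- function(scores, labels) {
  pos <- labels == "COPD"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  tpr <- rowMeans(scores[, pos, drop = FALSE])
  fpr <- rowMeans(scores[, !pos, drop = FALSE])
  # rank AUC of a binary feature = (TPR + (1 - FPR)) / 2
  (tpr + 1 - fpr) / 2
}

new_selection <- function(method, ranked, selected, params) {
  structure(list(method = method, ranked = ranked, selected = selected,
                 params = params),
            class = "mir_selection")
}

#' @export
print.mir_selection <- function(x, ...) {
  cat("<mir_selection> method: ", x$method, "; ", length(x$selected),
      " pair(s) selected of ", nrow(x$ranked), " ranked\n", sep = "")
  invisible(x)
}

#' @rdname auc_filter
#' @param x A `mir_selection`.
#' @param ... Unused.
#' @export
tidy.mir_selection <- function(x, ...) {
  dplyr::mutate(x$ranked, method = x$method,
                selected = .data$pair %in% x$selected, .before = 1)
}

#' @rdname auc_filter
#' @export
glance.mir_selection <- function(x, ...) {
  tibble::tibble(method = x$method, n_ranked = nrow(x$ranked),
                 n_selected = length(x$selected))
}

#' ROC filter: pairs whose direction-corrected AUC exceeds a threshold
#'
#' Ranks every pair by `max(AUC, 1 - AUC)` (descending; ties broken by
#' canonical pair order) and selects those strictly above `threshold`.
#'
#' @param pair_matrix A `mir_pairs`.
#' @param threshold AUC cutoff, default 0.7 (strict inequality).
#' @return A `mir_selection`; its `ranked` tibble carries both the raw and
#'   the direction-corrected AUC.
#' @export
auc_filter <- function(pair_matrix, threshold = 0.7) {
  stopifnot(inherits(pair_matrix, "mir_pairs"))
  check_two_classes(pair_matrix$labels)
  raw <- unname(matrix_binary_auc(pair_matrix$scores, pair_matrix$labels))
  ranked <- tibble::tibble(pair = pair_matrix$pairs,
                           auc = raw,
                           score = pmax(raw, 1 - raw)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$pair)
  new_selection("auc", ranked,
                selected = ranked$pair[ranked$score > threshold],
                params = list(threshold = threshold))
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
}

# Entropy in bits of an empirical distribution given by counts.
entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Mutual information in bits between two 0/1 (or factor-codable) vectors.
mutual_information_bits <- function(x, y) {
  tab <- table(x, y)
  entropy_bits(rowSums(tab)) + entropy_bits(colSums(tab)) - entropy_bits(tab)
}

# Vectorized I(X; Y) in bits for every row of a 0/1 matrix against the label.
matrix_mi_with_label <- function(scores, labels) {
  pos <- labels == "COPD"
  n <- length(labels)
  n1 <- sum(pos)
  a <- rowSums(scores[, pos, drop = FALSE])    # x=1, y=COPD
  b <- rowSums(scores) - a                     # x=1, y=healthy
  c1 <- n1 - a                                 # x=0, y=COPD
  d <- (n - n1) - b                            # x=0, y=healthy
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  hx <- -(plogp((a + b) / n) + plogp((c1 + d) / n))
  hy <- -(plogp(n1 / n) + plogp((n - n1) / n))
  hxy <- -(plogp(a / n) + plogp(b / n) + plogp(c1 / n) + plogp(d / n))
  hx + hy - hxy
}

#' Rank pairs by information gain
#'
#' Information gain of pair X for label Y is `H(Y) - H(Y|X)` (entropies in
#' bits from empirical frequencies) — the mutual information between the
#' binary feature and the diagnosis. Pairs are ranked descending, ties broken
#' by canonical pair order, and the top `k` selected.
#'
#' @param pair_matrix A `mir_pairs`.
#' @param k Number of pairs to select, default 20.
#' @return A `mir_selection` with per-pair information gain as `score`.
#' @export
information_gain_rank <- function(pair_matrix, k = 20) {
  stopifnot(inherits(pair_matrix, "mir_pairs"), k >= 1)
  check_two_classes(pair_matrix$labels)
  ig <- unname(matrix_mi_with_label(pair_matrix$scores, pair_matrix$labels))
  ranked <- tibble::tibble(pair = pair_matrix$pairs, score = ig) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$pair)
  new_selection("infogain", ranked,
                selected = head(ranked$pair, k),
                params = list(k = k))
}

#' Greedy minimum-redundancy maximum-relevance ranking
#'
#' The MID (mutual-information difference) scheme: the first pick maximizes
#' relevance `I(X; Y)`; each subsequent pick maximizes
#' `I(X; Y) - mean over selected Z of I(X; Z)`. All mutual information in
#' bits. Ties at any step are broken by canonical pair order. The `ranked`
#' tibble lists the picks in selection order with the criterion value at the
#' moment of selection.
#'
#' @param pair_matrix A `mir_pairs`.
#' @param k Number of pairs to pick, default 20.
#' @return A `mir_selection`.
#' @export
mrmr_rank <- function(pair_matrix, k = 20) {
  stopifnot(inherits(pair_matrix, "mir_pairs"), k >= 1)
  check_two_classes(pair_matrix$labels)
  scores <- pair_matrix$scores
  n_pairs <- nrow(scores)
  if (k > n_pairs) stop("k (", k, ") exceeds number of pairs (", n_pairs, ")",
                        call. = FALSE)
  relevance <- matrix_mi_with_label(scores, pair_matrix$labels)
  names(relevance) <- pair_matrix$pairs

  selected <- character(0)
  crit_vals <- numeric(0)
  redundancy_sum <- setNames(numeric(n_pairs), pair_matrix$pairs)
  remaining <- pair_matrix$pairs
  for (step in seq_len(k)) {
    crit <- if (step == 1) {
      relevance[remaining]
    } else {
      relevance[remaining] - redundancy_sum[remaining] / length(selected)
    }
    # max criterion, ties by canonical (lexicographic) pair id
    best <- sort(remaining[crit >= max(crit) - 1e-12])[1]
    selected <- c(selected, best)
    crit_vals <- c(crit_vals, unname(crit[best]))
    remaining <- setdiff(remaining, best)
    if (length(remaining) > 0 && step < k) {
      x_best <- scores[best, ]
      redundancy_sum[remaining] <- redundancy_sum[remaining] +
        vapply(remaining,
               function(p) mutual_information_bits(scores[p, ], x_best),
               numeric(1))
    }
  }
  ranked <- tibble::tibble(pair = selected, score = crit_vals)
  new_selection("mrmr", ranked, selected = selected, params = list(k = k))
}

#' Boruta all-relevant selection over pair features
#'
#' Implements the Boruta procedure: at each iteration every feature not yet
#' rejected is accompanied by `shadow_copies` "shadow" copies whose values
#' are independently permuted across samples, a random forest is fit on
#' real + shadow features, and a real feature scores a "hit" when its
#' importance exceeds the maximum shadow importance. After each iteration a
#' two-sided binomial test (p = 0.5) with Bonferroni correction over the
#' initial feature count confirms features whose hit counts are
#' significantly above chance and rejects those significantly below.
#' Iteration stops at `max_iter` or when no feature remains undecided.
#' Confirmed features are selected; features still undecided at termination
#' are reported as tentative and NOT selected.
#'
#' Importance is out-of-bag permutation importance scaled by its standard
#' error (ranger), from deliberately small forests: the per-iteration noise
#' in the importance estimate is what makes merely chance-correlated
#' features unable to beat the maximum of many shadows consistently, so the
#' binomial test rejects them, while genuinely predictive features win every
#' round regardless. Large forests with in-sample impurity importance make
#' sample-specific noise features look consistently "important" and inflate
#' false confirmations.
#'
#' @param pair_matrix A `mir_pairs` with >= 5 samples per class.
#' @param max_iter Maximum Boruta iterations, default 100.
#' @param alpha Significance level for the binomial decisions, default 0.05.
#' @param seed Integer seed controlling shadow permutations and forests.
#' @param num_trees Trees per random forest; `NULL` (default) scales with
#'   the feature count as `max(30, ceiling(n_features / 8))` so that large
#'   feature spaces are still explored.
#' @param shadow_copies Independently permuted shadow copies per feature;
#'   `NULL` (default) uses `max(3, ceiling(120 / n_features))`, so small
#'   feature spaces still get a stable shadow-maximum reference while large
#'   ones keep the cost linear.
#' @return A `mir_selection`; `ranked` holds per-feature hit fractions and a
#'   `decision` column (`confirmed` / `rejected` / `tentative`), `selected`
#'   the confirmed pairs.
#' @export
boruta_select <- function(pair_matrix, max_iter = 100, alpha = 0.05,
                          seed = 1L, num_trees = NULL, shadow_copies = NULL) {
  stopifnot(inherits(pair_matrix, "mir_pairs"), max_iter >= 1)
  check_two_classes(pair_matrix$labels)
  if (min(table(pair_matrix$labels)) < 5) {
    stop("need >= 5 samples per class for Boruta", call. = FALSE)
  }
  scores <- pair_matrix$scores
  if (all(rowSums(scores) %% ncol(scores) == 0)) {
    stop("all pair features have zero variance", call. = FALSE)
  }
  pairs <- pair_matrix$pairs
  m <- length(pairs)
  y <- pair_matrix$labels
  if (is.null(num_trees)) num_trees <- max(30, ceiling(m / 8))
  if (is.null(shadow_copies)) shadow_copies <- max(3, ceiling(120 / m))

  hits <- setNames(integer(m), pairs)
  decision <- setNames(rep("tentative", m), pairs)
  n_iter <- 0L

  withr::with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      undecided <- names(decision)[decision == "tentative"]
      if (length(undecided) == 0) break
      active <- names(decision)[decision != "rejected"]
      X <- t(scores[active, , drop = FALSE])
      shadow <- do.call(cbind, lapply(seq_len(shadow_copies),
                                      function(i) apply(X, 2, sample)))
      colnames(shadow) <- paste0("shadow_", seq_len(ncol(shadow)))
      df <- data.frame(X, shadow, check.names = FALSE)
      fit <- ranger::ranger(
        x = df, y = y, num.trees = num_trees, importance = "permutation",
        scale.permutation.importance = TRUE, num.threads = 1
      )
      imp <- fit$variable.importance
      shadow_max <- max(imp[colnames(shadow)])
      real_imp <- imp[active]
      hits[active[real_imp > shadow_max]] <-
        hits[active[real_imp > shadow_max]] + 1L
      n_iter <- iter

      # Bonferroni over the initial feature count, as in the reference scheme
      thr <- alpha / m
      h <- hits[undecided]
      p_more <- pbinom(h - 1L, iter, 0.5, lower.tail = FALSE)
      p_less <- pbinom(h, iter, 0.5)
      decision[undecided[p_more < thr / 2]] <- "confirmed"
      decision[undecided[p_less < thr / 2]] <- "rejected"
    }
  })

  ranked <- tibble::tibble(
    pair = pairs,
    score = as.numeric(hits) / max(n_iter, 1L),
    hits = as.integer(hits),
    decision = unname(decision)
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$pair)
  new_selection("boruta", ranked,
                selected = sort(names(decision)[decision == "confirmed"]),
                params = list(max_iter = max_iter, alpha = alpha, seed = seed,
                              num_trees = num_trees,
                              shadow_copies = shadow_copies,
                              iterations_run = n_iter))
}

#' Intersect the four selections into the consensus key pairs
#'
#' The key variables of the workflow are the pairs selected by *all four*
#' methods (ROC filter, information gain, MRMR, Boruta). Pairwise overlap
#' counts between methods are reported for Venn-style summaries.
#'
#' @param results A list of four `mir_selection` objects, one per method
#'   (`auc`, `infogain`, `mrmr`, `boruta`), in any order.
#' @return An object of class `mir_consensus` with elements `per_method`,
#'   `key_pairs`, and `overlap` (a method x method count matrix).
#' @export
intersect_selections <- function(results) {
  stopifnot(is.list(results))
  for (r in results) stopifnot(inherits(r, "mir_selection"))
  methods <- vapply(results, function(r) r$method, character(1))
  expected <- c("auc", "infogain", "mrmr", "boruta")
  if (!setequal(methods, expected) || length(methods) != 4) {
    stop("need exactly one selection per method: ",
         paste(expected, collapse = ", "), "; got: ",
         paste(methods, collapse = ", "), call. = FALSE)
  }
  names(results) <- methods
  results <- results[expected]
  sets <- lapply(results, function(r) r$selected)
  key <- sort(Reduce(intersect, sets))
  overlap <- outer(expected, expected,
                   Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]]))))
  dimnames(overlap) <- list(expected, expected)
  structure(list(per_method = results, key_pairs = key, overlap = overlap),
            class = "mir_consensus")
}

#' @export
print.mir_consensus <- function(x, ...) {
  cat("<mir_consensus> key pairs (in all four selections):",
      length(x$key_pairs), "\n")
  if (length(x$key_pairs) > 0) {
    cat("  ", paste(x$key_pairs, collapse = ", "), "\n", sep = "")
  }
  sizes <- vapply(x$per_method, function(r) length(r$selected), integer(1))
  cat("  per-method counts: ",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname intersect_selections
#' @param x A `mir_consensus`.
#' @param ... Unused.
#' @export
tidy.mir_consensus <- function(x, ...) {
  purrr::map_dfr(x$per_method, function(r) {
    tibble::tibble(method = r$method, pair = r$selected)
  }) |>
    dplyr::mutate(key_pair = .data$pair %in% x$key_pairs)
}

#' @rdname intersect_selections
#' @export
glance.mir_consensus <- function(x, ...) {
  sizes <- vapply(x$per_method, function(r) length(r$selected), integer(1))
  tibble::tibble(n_auc = sizes[["auc"]], n_infogain = sizes[["infogain"]],
                 n_mrmr = sizes[["mrmr"]], n_boruta = sizes[["boruta"]],
                 n_key_pairs = length(x$key_pairs))
}

#' Run all four selectors and intersect them
#'
#' Convenience driver: ROC filter, information gain, MRMR and Boruta on the
#' same pair matrix, then [intersect_selections()]. Parameters and the Boruta
#' seed are recorded in the result's `params`.
#'
#' @param pair_matrix A `mir_pairs`.
#' @param auc_threshold ROC-filter cutoff (default 0.7).
#' @param k Top-k for information gain and MRMR (default 20).
#' @param seed Seed for the Boruta forests/permutations.
#' @param boruta_max_iter,boruta_num_trees Boruta iteration and forest-size
#'   controls (see [boruta_select()]).
#' @param alpha Boruta significance level.
#' @return A `mir_consensus` (with a `params` attribute recording the run
#'   configuration).
#' @export
run_consensus <- function(pair_matrix, auc_threshold = 0.7, k = 20, seed = 1L,
                          boruta_max_iter = 50, boruta_num_trees = NULL,
                          alpha = 0.05) {
  res <- list(
    auc_filter(pair_matrix, threshold = auc_threshold),
    information_gain_rank(pair_matrix, k = k),
    mrmr_rank(pair_matrix, k = min(k, nrow(pair_matrix$scores))),
    boruta_select(pair_matrix, max_iter = boruta_max_iter, alpha = alpha,
                  seed = seed, num_trees = boruta_num_trees)
  )
  out <- intersect_selections(res)
  attr(out, "params") <- list(auc_threshold = auc_threshold, k = k, seed = seed,
                              boruta_max_iter = boruta_max_iter,
                              boruta_num_trees = boruta_num_trees, alpha = alpha)
  out
}
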