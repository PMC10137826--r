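#' Stratified train/test split
#'
#' Per class, `floor(train_frac * n_class)` samples are drawn uniformly
#' without replacement into the training partition; the remainder form the
#' test partition. With 63 COPD + 110 healthy at 0.7 this yields the
#' canonical 121/52 split (44 + 77 train, 19 + 33 test). Deterministic given
#' `seed`.
#'
#' @param labels Named class vector (names = sample IDs) or a `mir_pairs` /
#'   `mir_cohort` object.
#' @param train_frac Training fraction, default 0.7.
#' @param seed Integer seed.
#' @return An object of class `mir_split` with `train_ids`, `test_ids`, and a
#'   per-class count table.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  if (inherits(labels, "mir_pairs") || inherits(labels, "mir_cohort")) {
    labels <- labels$labels
  }
  labels <- as_class_factor(labels)
  if (is.null(names(labels))) names(labels) <- paste0("S", seq_along(labels))
  stopifnot(train_frac > 0, train_frac < 1)
  check_two_classes(labels)

  train_ids <- withr::with_seed(seed, {
    unlist(lapply(.mirpair_classes, function(cl) {
      ids <- names(labels)[labels == cl]
      n_tr <- floor(train_frac * length(ids))
      if (n_tr == 0 || n_tr == length(ids)) {
        stop("class '", cl, "' would have an empty train or test partition",
             call. = FALSE)
      }
      sort(sample(ids, n_tr))
    }), use.names = FALSE)
  })
  test_ids <- setdiff(names(labels), train_ids)
  counts <- tibble::tibble(
    class = rep(.mirpair_classes, 2),
    partition = rep(c("train", "test"), each = 2),
    n = c(sum(labels[train_ids] == "healthy"), sum(labels[train_ids] == "COPD"),
          sum(labels[test_ids] == "healthy"), sum(labels[test_ids] == "COPD"))
  )
  structure(list(train_ids = train_ids, test_ids = test_ids, counts = counts,
                 train_frac = train_frac, seed = seed),
            class = "mir_split")
}

#' @export
print.mir_split <- function(x, ...) {
  cat("<mir_split> train n=", length(x$train_ids), ", test n=",
      length(x$test_ids), " (train_frac=", x$train_frac, ", seed=", x$seed,
      ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @rdname stratified_split
#' @param x A `mir_split`.
#' @param ... Unused.
#' @export
tidy.mir_split <- function(x, ...) x$counts

# ---------------------------------------------------------------------------
# Algorithm wrappers: each entry provides fit(X, y, params) -> handle and
# prob(handle, X) -> P(COPD). X is a samples x features numeric matrix.

#' The seven supported classification algorithms
#'
#' @return Character vector of algorithm names accepted by
#'   [train_classifier()].
#' @export
supported_algorithms <- function() {
  c("knn", "svm", "random_forest", "naive_bayes", "decision_tree",
    "xgboost", "logistic")
}

#' Default hyperparameter grids
#'
#' Small per-algorithm grids used by [train_classifier()] when none is
#' supplied. Each grid is a data frame, one row per candidate configuration;
#' callers can pass their own in the same shape.
#'
#' @param algorithm One of `knn`, `svm`, `random_forest`, `naive_bayes`,
#'   `decision_tree`, `xgboost`, `logistic`.
#' @return A data frame of hyperparameter combinations.
#' @export
default_grid <- function(algorithm) {
  switch(
    match.arg(algorithm, supported_algorithms()),
    knn = expand.grid(k = c(3, 5, 7, 9)),
    svm = expand.grid(cost = c(0.1, 1, 10), gamma = c(0.1, 0.5)),
    random_forest = expand.grid(num_trees = 500, mtry_frac = c(0.33, 0.6, 1)),
    naive_bayes = expand.grid(laplace = c(0, 0.5, 1)),
    decision_tree = expand.grid(cp = c(0.001, 0.01, 0.05), minsplit = c(5, 10)),
    xgboost = expand.grid(nrounds = c(50, 100), max_depth = c(2, 3),
                          eta = c(0.1, 0.3)),
    logistic = expand.grid(alpha = c(0, 0.5, 1), lambda = c(0.001, 0.01, 0.1))
  )
}

fit_algorithm <- function(algorithm, X, y, params) {
  p <- as.list(params)
  switch(
    algorithm,
    knn = list(X = X, y = y, k = p$k),  # lazy learner: store training data
    svm = e1071::svm(x = X, y = y, cost = p$cost, gamma = p$gamma,
                     kernel = "radial"),
    random_forest = randomForest::randomForest(
      x = X, y = y, ntree = p$num_trees,
      mtry = max(1, floor(p$mtry_frac * ncol(X)))
    ),
    naive_bayes = e1071::naiveBayes(x = X, y = y, laplace = p$laplace),
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(y = y, X, check.names = FALSE),
      method = "class",
      control = rpart::rpart.control(cp = p$cp, minsplit = p$minsplit)
    ),
    xgboost = xgboost::xgboost(
      X, y, nrounds = p$nrounds, max_depth = p$max_depth,
      learning_rate = p$eta, objective = "binary:logistic",
      nthreads = 1, verbosity = 0
    ),
    logistic = glmnet::glmnet(x = X, y = y, family = "binomial",
                              alpha = p$alpha, lambda = p$lambda),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

prob_algorithm <- function(algorithm, handle, X) {
  # models may be deserialized in a fresh session: make sure the learner's
  # namespace (and its S3 predict methods) is loaded before dispatch
  ns <- switch(algorithm, svm = "e1071", naive_bayes = "e1071",
               random_forest = "randomForest", decision_tree = "rpart",
               xgboost = "xgboost", logistic = "glmnet", NULL)
  if (!is.null(ns)) requireNamespace(ns, quietly = TRUE)
  switch(
    algorithm,
    knn = knn_prob(handle, X),
    svm = {
      # decision values mapped through a logistic link: Platt's sigmoid fit
      # is unstable on small or separable folds and can invert orientation
      pred <- predict(handle, X, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      sign <- if (grepl("^COPD", colnames(dv)[1])) 1 else -1
      unname(stats::plogis(sign * dv[, 1]))
    },
    random_forest = unname(predict(handle, X, type = "prob")[, "COPD"]),
    naive_bayes = unname(predict(handle, X, type = "raw")[, "COPD"]),
    decision_tree = unname(
      predict(handle, data.frame(X, check.names = FALSE), type = "prob")[, "COPD"]
    ),
    xgboost = unname(predict(handle, X, type = "response")),
    logistic = as.numeric(predict(handle, X, type = "response")),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

# k-NN vote fractions as probabilities; deterministic distance-tie handling
# comes from class::knn's use.all voting.
knn_prob <- function(handle, X) {
  pred <- class::knn(train = handle$X, test = X, cl = handle$y, k = handle$k,
                     prob = TRUE, use.all = TRUE)
  p_win <- attr(pred, "prob")
  ifelse(pred == "COPD", p_win, 1 - p_win)
}

# Stratified fold assignment: per class, shuffled samples dealt round-robin.
stratified_folds <- function(y, folds) {
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' Train and tune a classifier on key-pair features
#'
#' Grid search over hyperparameters, scored by mean AUC across stratified
#' cross-validation folds on the *training* partition only; the grid point
#' with the highest mean CV AUC wins (ties: first-listed row). The winner is
#' refit on the full training partition. The fitted model stores its ordered
#' pair-feature schema; prediction later requires exactly those pairs.
#'
#' @param pair_matrix A `mir_pairs` restricted to the key pairs (rows become
#'   the model's feature schema, in order).
#' @param split A [stratified_split()] result.
#' @param algorithm One of [supported_algorithms()]'s seven names.
#' @param grid Data frame of hyperparameter rows; `NULL` for
#'   [default_grid()].
#' @param folds CV folds for tuning, default 10.
#' @param seed Seed for fold assignment and stochastic learners.
#' @return An object of class `mir_model` with elements `algorithm`,
#'   `feature_schema`, `tuned_params`, `cv_summary` (fold-level AUCs per grid
#'   row), and the fitted handle.
#' @export
train_classifier <- function(pair_matrix, split, algorithm, grid = NULL,
                             folds = 10, seed = 1L) {
  stopifnot(inherits(pair_matrix, "mir_pairs"), inherits(split, "mir_split"))
  algorithm <- match.arg(algorithm, supported_algorithms())
  if (is.null(grid)) grid <- default_grid(algorithm)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)

  schema <- pair_matrix$pairs
  X_all <- t(pair_matrix$scores)
  storage.mode(X_all) <- "double"
  tr <- split$train_ids
  missing_tr <- setdiff(tr, rownames(X_all))
  if (length(missing_tr) > 0) {
    stop("split references samples absent from the pair matrix: ",
         paste(head(missing_tr, 5), collapse = ", "), call. = FALSE)
  }
  X <- X_all[tr, , drop = FALSE]
  y <- pair_matrix$labels[tr]

  cv <- withr::with_seed(seed, {
    fold_of <- stratified_folds(y, folds)
    degenerate <- vapply(seq_len(folds), function(f) {
      length(unique(y[fold_of == f])) < 2 || sum(fold_of == f) == 0
    }, logical(1))
    if (any(degenerate)) {
      stop("fold(s) with a single class; use fewer folds for this class balance",
           call. = FALSE)
    }
    purrr::map_dfr(seq_len(nrow(grid)), function(g) {
      aucs <- vapply(seq_len(folds), function(f) {
        in_f <- fold_of == f
        h <- fit_algorithm(algorithm, X[!in_f, , drop = FALSE], y[!in_f],
                           grid[g, , drop = FALSE])
        pr <- prob_algorithm(algorithm, h, X[in_f, , drop = FALSE])
        rank_auc(pr, y[in_f] == "COPD")
      }, numeric(1))
      tibble::tibble(grid_row = g, fold = seq_len(folds), cv_auc = aucs)
    })
  })
  means <- cv |>
    dplyr::summarise(mean_auc = mean(.data$cv_auc), .by = "grid_row")
  best <- means$grid_row[which.max(means$mean_auc)]  # first max = first-listed
  tuned <- grid[best, , drop = FALSE]

  handle <- withr::with_seed(seed, fit_algorithm(algorithm, X, y, tuned))
  structure(
    list(algorithm = algorithm, feature_schema = schema,
         tuned_params = as.list(tuned),
         cv_summary = dplyr::left_join(
           cv, dplyr::bind_cols(grid_row = seq_len(nrow(grid)),
                                tibble::as_tibble(grid)),
           by = "grid_row"),
         mean_cv_auc = max(means$mean_auc),
         handle = handle, folds = folds, seed = seed,
         classes = .mirpair_classes),
    class = "mir_model"
  )
}

#' @export
print.mir_model <- function(x, ...) {
  cat("<mir_model> ", x$algorithm, " on ", length(x$feature_schema),
      " pair feature(s)\n", sep = "")
  cat("  tuned: ",
      paste(names(x$tuned_params), unlist(x$tuned_params), sep = "=",
            collapse = ", "),
      "; mean CV AUC = ", round(x$mean_cv_auc, 3), " (", x$folds, " folds)\n",
      sep = "")
  invisible(x)
}

#' @rdname train_classifier
#' @param x A `mir_model`.
#' @param ... Unused.
#' @export
tidy.mir_model <- function(x, ...) x$cv_summary

#' @rdname train_classifier
#' @export
glance.mir_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(algorithm = x$algorithm,
                   n_features = length(x$feature_schema),
                   folds = x$folds, mean_cv_auc = x$mean_cv_auc),
    tibble::as_tibble(x$tuned_params)
  )
}

#' Predict COPD probabilities from a fitted model
#'
#' @param object A `mir_model`.
#' @param newdata A `mir_pairs` or a samples x pairs 0/1 matrix whose columns
#'   cover the model's feature schema.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `p_copd`, `predicted_class`
#'   (COPD iff `p_copd >= 0.5`).
#' @export
predict.mir_model <- function(object, newdata, ...) {
  if (inherits(newdata, "mir_pairs")) {
    X <- t(newdata$scores)
  } else {
    X <- as.matrix(newdata)
  }
  storage.mode(X) <- "double"
  missing_pairs <- setdiff(object$feature_schema, colnames(X))
  if (length(missing_pairs) > 0) {
    stop("input lacks schema pair(s): ",
         paste(missing_pairs, collapse = ", "), call. = FALSE)
  }
  X <- X[, object$feature_schema, drop = FALSE]
  p <- prob_algorithm(object$algorithm, object$handle, X)
  tibble::tibble(
    sample = rownames(X) %||% paste0("S", seq_len(nrow(X))),
    p_copd = p,
    predicted_class = ifelse(p >= 0.5, "COPD", "healthy")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Diagnostic metrics

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity, specificity, PPV, NPV and overall accuracy from the four
#' confusion-matrix counts (COPD positive). Full precision is retained; the
#' print method rounds to 3 decimals.
#'
#' @param tp,fn,tn,fp Non-negative integer counts.
#' @return A one-row tibble of class `mir_metrics`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  if (tp + fn == 0) stop("no positive samples: sensitivity undefined", call. = FALSE)
  if (tn + fp == 0) stop("no negative samples: specificity undefined", call. = FALSE)
  out <- tibble::tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    accuracy = (tp + tn) / (tp + fn + tn + fp)
  )
  class(out) <- c("mir_metrics", class(out))
  out
}

#' @export
print.mir_metrics <- function(x, ...) {
  y <- tibble::as_tibble(x)
  num <- vapply(y, is.double, logical(1))
  y[num] <- lapply(y[num], round, digits = 3)
  print(y)
  invisible(x)
}

#' AUC with a DeLong 95% confidence interval
#'
#' Point estimate by the tie-corrected rank (Mann-Whitney) statistic for
#' COPD as the positive class; 95% CI by DeLong's variance estimate,
#' truncated to [0, 1]. Constant scores yield AUC 0.5 with a degenerate
#' (NA) CI and a warning.
#'
#' @param scores Numeric prediction scores (larger = more COPD-like).
#' @param labels Class vector.
#' @return A one-row tibble with `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc_ci <- function(scores, labels) {
  labels <- as_class_factor(labels)
  check_two_classes(labels)
  stopifnot(all(is.finite(scores)))
  if (length(unique(scores)) == 1) {
    warning("constant scores: AUC 0.5 with degenerate CI", call. = FALSE)
    return(tibble::tibble(auc = 0.5, ci_low = NA_real_, ci_high = NA_real_))
  }
  auc <- rank_auc(scores, labels == "COPD")
  roc <- pROC::roc(response = labels, predictor = scores, levels = .mirpair_classes,
                   direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
  tibble::tibble(auc = auc,
                 ci_low = max(0, ci[1]),
                 ci_high = min(1, ci[3]))
}

#' Evaluate a fitted model on a sample partition
#'
#' Predicts COPD probabilities, assigns classes at the 0.5 threshold, and
#' assembles the confusion counts, derived rates, and AUC with DeLong CI.
#'
#' @param model A `mir_model`.
#' @param pair_matrix A `mir_pairs` covering the model's schema.
#' @param samples Sample IDs to evaluate on (e.g. `split$test_ids`), or
#'   `NULL` for all samples in `pair_matrix`.
#' @param in_sample Set `TRUE` when evaluating on training samples; recorded
#'   in the result so in-sample numbers are never mistaken for test numbers.
#' @return A `mir_metrics` tibble with counts, rates, `auc`, `ci_low`,
#'   `ci_high`, and a `partition` column; per-sample predictions are attached
#'   as attribute `"predictions"`.
#' @export
evaluate_classifier <- function(model, pair_matrix, samples = NULL,
                                in_sample = FALSE) {
  stopifnot(inherits(model, "mir_model"), inherits(pair_matrix, "mir_pairs"))
  if (is.null(samples)) samples <- colnames(pair_matrix$scores)
  missing_s <- setdiff(samples, colnames(pair_matrix$scores))
  if (length(missing_s) > 0) {
    stop("sample(s) absent from pair matrix: ",
         paste(head(missing_s, 5), collapse = ", "), call. = FALSE)
  }
  X <- t(pair_matrix$scores[, samples, drop = FALSE])
  preds <- predict(model, X)
  truth <- as.character(pair_matrix$labels[samples])
  preds$truth <- truth

  tp <- sum(preds$predicted_class == "COPD" & truth == "COPD")
  fn <- sum(preds$predicted_class == "healthy" & truth == "COPD")
  tn <- sum(preds$predicted_class == "healthy" & truth == "healthy")
  fp <- sum(preds$predicted_class == "COPD" & truth == "healthy")
  metrics <- confusion_metrics(tp, fn, tn, fp)
  aucs <- if (length(unique(preds$p_copd)) == 1) {
    tibble::tibble(auc = 0.5, ci_low = NA_real_, ci_high = NA_real_)
  } else {
    roc_auc_ci(preds$p_copd, truth)
  }
  out <- dplyr::bind_cols(metrics, aucs)
  out$partition <- if (in_sample) "in_sample" else "held_out"
  class(out) <- c("mir_metrics", "tbl_df", "tbl", "data.frame")
  attr(out, "predictions") <- preds
  out
}
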