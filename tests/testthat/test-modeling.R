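test_that("stratified_split reproduces the canonical 70/30 composition", {
  labels <- setNames(rep(c("COPD", "healthy"), c(63, 110)), paste0("S", 1:173))
  for (seed in c(1, 2, 17, 42, 99)) {
    sp <- stratified_split(labels, 0.7, seed = seed)
    expect_length(sp$train_ids, 121)
    expect_length(sp$test_ids, 52)
    expect_equal(sum(labels[sp$test_ids] == "COPD"), 19)
    expect_equal(sum(labels[sp$test_ids] == "healthy"), 33)
  }

  # 10 + 10 at 0.5
  lab2 <- setNames(rep(c("COPD", "healthy"), each = 10), paste0("T", 1:20))
  sp2 <- stratified_split(lab2, 0.5, seed = 3)
  expect_equal(sum(lab2[sp2$train_ids] == "COPD"), 5)
  expect_equal(sum(lab2[sp2$train_ids] == "healthy"), 5)

  # determinism and seed sensitivity
  expect_identical(stratified_split(labels, 0.7, seed = 7),
                   stratified_split(labels, 0.7, seed = 7))
  expect_false(identical(stratified_split(labels, 0.7, seed = 7)$train_ids,
                         stratified_split(labels, 0.7, seed = 8)$train_ids))

  # degenerate partitions rejected
  lab3 <- setNames(c("COPD", rep("healthy", 9)), paste0("U", 1:10))
  expect_error(stratified_split(lab3, 0.7, seed = 1), "empty train or test")
})

test_that("confusion_metrics reproduces the published worked examples exactly", {
  m <- confusion_metrics(15, 4, 29, 4)
  expect_equal(round(m$sensitivity, 3), 0.789)
  expect_equal(round(m$specificity, 3), 0.879)
  expect_equal(round(m$accuracy, 3), 0.846)

  m2 <- confusion_metrics(20, 5, 14, 6)
  expect_equal(m2$sensitivity, 0.8)
  expect_equal(m2$specificity, 0.7)

  m3 <- confusion_metrics(10, 0, 10, 0)
  expect_equal(unlist(m3[c("sensitivity", "specificity", "ppv", "npv", "accuracy")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1, accuracy = 1))

  expect_error(confusion_metrics(0, 0, 5, 5), "sensitivity")
  expect_error(confusion_metrics(5, 5, 0, 0), "specificity")
})

test_that("metric identities hold on random confusion tables", {
  for (seed in 1:20) {
    withr::local_seed(seed)
    cnt <- rmultinom(1, size = sample(20:200, 1), prob = runif(4, 0.05, 1))[, 1]
    tp <- cnt[1] + 1; fn <- cnt[2]; tn <- cnt[3] + 1; fp <- cnt[4]
    m <- confusion_metrics(tp, fn, tn, fp)
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$ppv, tp / (tp + fp))
    if (tn + fn > 0) expect_equal(m$npv, tn / (tn + fn))
    expect_equal(m$accuracy, (tp + tn) / sum(c(tp, fn, tn, fp)))
  }
})

test_that("roc_auc_ci equals the concordance oracle and behaves at the edges", {
  labels <- rep(c("COPD", "healthy"), each = 10)
  perfect <- c(rep(1, 10), rep(0, 10))
  expect_equal(roc_auc_ci(perfect, labels)$auc, 1.0)

  # one swapped pair among 10+10
  swapped <- perfect; swapped[c(1, 11)] <- swapped[c(11, 1)]
  res <- roc_auc_ci(swapped, labels)
  expect_equal(res$auc, auc_oracle(swapped, labels))
  expect_true(res$ci_low <= res$auc && res$auc <= res$ci_high)

  for (seed in 1:15) {
    withr::local_seed(seed)
    n <- sample(8:30, 1)
    lab <- sample(rep(c("COPD", "healthy"), length.out = n))
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(n), 1)  # rounding induces ties
    expect_equal(roc_auc_ci(sc, lab)$auc, auc_oracle(sc, lab))
  }

  expect_warning(res0 <- roc_auc_ci(rep(0.5, 20), labels), "constant")
  expect_equal(res0$auc, 0.5)
  expect_true(is.na(res0$ci_low))
})

test_that("DeLong interval covers the binormal AUC at nominal rate", {
  # analytic AUC for a Gaussian shift d is pnorm(d / sqrt(2))
  d <- 1
  target <- pnorm(d / sqrt(2))
  covered <- vapply(1:60, function(seed) {
    withr::local_seed(seed)
    n <- 120
    lab <- rep(c("COPD", "healthy"), each = n / 2)
    sc <- c(rnorm(n / 2, d), rnorm(n / 2, 0))
    ci <- roc_auc_ci(sc, lab)
    ci$ci_low <= target && target <= ci$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.85)  # ~95% nominal, Monte-Carlo slack
})

test_that("a label-identical feature gives CV AUC 1 for every algorithm", {
  withr::local_seed(1)
  n <- 60
  labels <- setNames(sample(rep(c("COPD", "healthy"), each = n / 2)),
                     paste0("S", 1:n))
  sig <- as.integer(labels == "COPD")
  scores <- rbind(sig, matrix(rbinom(4 * n, 1, 0.5), nrow = 4))
  rownames(scores) <- c("s|t", paste0("a", 1:4, "|b", 1:4))
  colnames(scores) <- names(labels)
  pm <- mirpair:::new_pair_matrix(scores, labels)
  sp <- stratified_split(labels, 0.7, seed = 1)

  for (alg in supported_algorithms()) {
    grid <- default_grid(alg)[1, , drop = FALSE]
    m <- train_classifier(pm, sp, alg, grid = grid, folds = 5, seed = 1)
    expect_equal(m$mean_cv_auc, 1.0, tolerance = 1e-9)
  }
})

test_that("shuffled labels give near-chance mean CV AUC for every algorithm", {
  seeds <- 1:8
  for (alg in supported_algorithms()) {
    aucs <- vapply(seeds, function(seed) {
      withr::local_seed(seed)
      n <- 120
      labels <- setNames(sample(rep(c("COPD", "healthy"), each = n / 2)),
                         paste0("S", 1:n))
      scores <- matrix(rbinom(5 * n, 1, 0.5), nrow = 5,
                       dimnames = list(paste0("a", 1:5, "|b", 1:5),
                                       names(labels)))
      pm <- mirpair:::new_pair_matrix(scores, labels)
      sp <- stratified_split(labels, 0.7, seed = seed)
      m <- train_classifier(pm, sp, alg,
                            grid = default_grid(alg)[1, , drop = FALSE],
                            folds = 10, seed = seed)
      m$mean_cv_auc
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.15)
  }
})

test_that("grid ties break to the first-listed point and folds must be sane", {
  withr::local_seed(2)
  n <- 40
  labels <- setNames(rep(c("COPD", "healthy"), each = n / 2), paste0("S", 1:n))
  sig <- as.integer(labels == "COPD")
  scores <- matrix(sig, 1, dimnames = list("s|t", names(labels)))
  pm <- mirpair:::new_pair_matrix(scores, labels)
  sp <- stratified_split(labels, 0.7, seed = 2)

  # separable data: every k ties at AUC 1; the first k must win
  m <- train_classifier(pm, sp, "knn", grid = data.frame(k = c(7, 3, 5)),
                        folds = 4, seed = 2)
  expect_equal(m$tuned_params$k, 7)

  expect_error(train_classifier(pm, sp, "knn", folds = 40, seed = 1),
               "single class|fewer folds")
  expect_error(train_classifier(pm, sp, "nonesuch"), "arg")
})

test_that("evaluation assembles counts, rates and AUC on held-out samples", {
  withr::local_seed(3)
  n <- 80
  labels <- setNames(sample(rep(c("COPD", "healthy"), each = n / 2)),
                     paste0("S", 1:n))
  sig <- as.integer(labels == "COPD")
  noisy <- sig; flip <- sample(n, 8); noisy[flip] <- 1L - noisy[flip]
  scores <- rbind(matrix(noisy, 1), matrix(rbinom(2 * n, 1, 0.5), nrow = 2))
  rownames(scores) <- c("s|t", "a|b", "c|d")
  colnames(scores) <- names(labels)
  pm <- mirpair:::new_pair_matrix(scores, labels)
  sp <- stratified_split(labels, 0.7, seed = 3)

  m <- train_classifier(pm, sp, "random_forest",
                        grid = data.frame(num_trees = 200, mtry_frac = 1),
                        folds = 5, seed = 3)
  ev <- evaluate_classifier(m, pm, sp$test_ids)
  expect_equal(ev$tp + ev$fn, sum(labels[sp$test_ids] == "COPD"))
  expect_equal(ev$tn + ev$fp, sum(labels[sp$test_ids] == "healthy"))
  expect_equal(ev$accuracy, (ev$tp + ev$tn) / length(sp$test_ids))
  expect_equal(ev$partition, "held_out")

  # in-sample evaluation on a separable fixture reaches accuracy 1, flagged
  sep <- pm
  sep$scores <- rbind(pm$scores,
                      matrix(as.integer(labels == "COPD"), 1,
                             dimnames = list("z|w", names(labels))))
  sep$pairs <- rownames(sep$scores)
  m_sep <- train_classifier(sep, sp, "decision_tree",
                            grid = data.frame(cp = 0.01, minsplit = 5),
                            folds = 5, seed = 3)
  ev_in <- evaluate_classifier(m_sep, sep, sp$train_ids, in_sample = TRUE)
  expect_equal(ev_in$partition, "in_sample")
  expect_equal(ev_in$accuracy, 1.0)

  # schema mismatch is named
  pm_missing <- pm
  pm_missing$scores <- pm$scores[-1, , drop = FALSE]
  pm_missing$pairs <- rownames(pm_missing$scores)
  expect_error(predict(m, pm_missing), "s\\|t")
})

test_that("predictions are invariant to monotone transforms of the raw cohort", {
  co <- random_cohort(n_feat = 8, n_samp = 30, seed = 11)
  pm <- build_pair_matrix(co)
  sp <- stratified_split(pm$labels, 0.7, seed = 4)
  m <- train_classifier(pm, sp, "naive_bayes",
                        grid = data.frame(laplace = 0.5), folds = 3, seed = 4)
  co2 <- co; co2$values <- exp(co$values / 50)  # strictly increasing
  pm2 <- build_pair_matrix(co2)
  expect_identical(predict(m, pm), predict(m, pm2))
})
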