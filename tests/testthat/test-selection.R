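test_that("binary_feature_auc equals the Mann-Whitney concordance oracle", {
  # worked 6-sample example: COPD scores 1,1,0; healthy 0,0,1
  scores <- c(1, 1, 0, 0, 0, 1)
  labels <- rep(c("COPD", "healthy"), each = 3)
  res <- binary_feature_auc(scores, labels)
  expect_equal(res$auc, 2 / 3)
  expect_equal(res$auc, auc_oracle(scores, labels))

  # perfect separation and independence
  lab <- rep(c("COPD", "healthy"), each = 10)
  expect_equal(binary_feature_auc(as.integer(lab == "COPD"), lab)$auc, 1.0)
  expect_equal(binary_feature_auc(rep(c(0, 1), 10), lab)$auc, 0.5)

  # random instances
  for (seed in 1:25) {
    withr::local_seed(seed)
    n <- sample(6:30, 1)
    lab <- sample(rep(c("COPD", "healthy"), length.out = n))
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(lab)) < 2) next
    expect_equal(binary_feature_auc(x, lab)$auc, auc_oracle(x, lab))
  }

  expect_error(binary_feature_auc(c(0, 1), c("COPD", "COPD")), "both classes")
})

test_that("auc_filter selects strictly above threshold, direction-corrected", {
  withr::local_seed(1)
  n <- 120
  labels <- rep(c("COPD", "healthy"), each = n / 2)
  perfect <- as.integer(labels == "COPD")
  nulls <- matrix(rbinom(50 * n, 1, 0.5), nrow = 50)
  scores <- rbind(perfect, 1L - perfect, nulls)
  rownames(scores) <- c("pp|qq", "rr|ss", paste0("n", 1:50, "|m", 1:50))
  pm <- make_pm(scores, labels)

  sel <- auc_filter(pm, threshold = 0.7)
  expect_true("pp|qq" %in% sel$selected)
  # reversed-orientation perfect pair is rescued by direction correction
  expect_true("rr|ss" %in% sel$selected)
  expect_equal(sel$ranked$score[1], 1.0)
  # raw AUC kept in the report
  expect_equal(sel$ranked$auc[sel$ranked$pair == "rr|ss"], 0.0)

  # threshold 1.0 with strict inequality: nothing survives once imperfect
  scores2 <- scores; scores2["pp|qq", 1] <- 0L; scores2["rr|ss", 1] <- 1L
  sel2 <- auc_filter(make_pm(scores2, labels), threshold = 1.0)
  expect_length(sel2$selected, 0)
})

test_that("label permutation leaves almost nothing above the AUC threshold", {
  counts <- vapply(1:20, function(seed) {
    withr::local_seed(seed)
    n <- 120
    labels <- sample(rep(c("COPD", "healthy"), each = n / 2))
    scores <- matrix(rbinom(60 * n, 1, 0.5), nrow = 60,
                     dimnames = list(paste0("a", 1:60, "|b", 1:60), NULL))
    length(auc_filter(make_pm(scores, labels), 0.7)$selected)
  }, numeric(1))
  expect_lt(mean(counts), 1)
})

test_that("information gain matches direct entropy arithmetic", {
  # 2x2 worked table: COPD 8 ones / 2 zeros; healthy 3 ones / 7 zeros
  x <- c(rep(1, 8), rep(0, 2), rep(1, 3), rep(0, 7))
  y <- rep(c("COPD", "healthy"), each = 10)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hy <- h(c(0.5, 0.5))
  # H(Y|X): X=1 in 11 samples (8 COPD), X=0 in 9 (2 COPD)
  hy_given_x <- (11 / 20) * h(c(8 / 11, 3 / 11)) + (9 / 20) * h(c(2 / 9, 7 / 9))
  expected_ig <- hy - hy_given_x

  scores <- matrix(x, 1, dimnames = list("a|b", NULL))
  sel <- information_gain_rank(make_pm(scores, y), k = 1)
  expect_equal(sel$ranked$score, expected_ig)
  expect_equal(sel$ranked$score, mi_oracle(x, y))

  # perfectly predictive pair with balanced classes: 1 bit
  perfect <- matrix(as.integer(y == "COPD"), 1, dimnames = list("p|q", NULL))
  expect_equal(information_gain_rank(make_pm(perfect, y), 1)$ranked$score, 1.0)

  # independent pair: 0 bits
  indep <- matrix(rep(c(0L, 1L), 10), 1, dimnames = list("i|j", NULL))
  expect_equal(information_gain_rank(make_pm(indep, y), 1)$ranked$score, 0.0)
})

test_that("information gain is bounded by min(H(X), H(Y)) and non-negative", {
  for (seed in 1:10) {
    withr::local_seed(seed)
    n <- 40
    y <- sample(rep(c("COPD", "healthy"), each = n / 2))
    x <- rbinom(n, 1, runif(1, 0.1, 0.9))
    scores <- matrix(x, 1, dimnames = list("a|b", NULL))
    ig <- information_gain_rank(make_pm(scores, y), 1)$ranked$score
    h <- function(p) { p <- p[p > 0 & p < 1]; if (!length(p)) 0 else -sum(c(p, 1 - p) * log2(c(p, 1 - p))) }
    expect_gte(ig, 0)
    expect_lte(ig, min(h(mean(x)), 1) + 1e-12)
  }
})

test_that("MRMR penalizes redundancy and agrees with infogain at k = 1", {
  withr::local_seed(2)
  n <- 60
  y <- rep(c("COPD", "healthy"), each = n / 2)
  strong <- as.integer(y == "COPD"); strong[1:6] <- 1L - strong[1:6]
  weak <- as.integer(y == "COPD"); weak[1:20] <- 1L - weak[1:20]
  scores <- rbind(strong, strong, weak)
  rownames(scores) <- c("a|b", "c|d", "e|f")  # a|b and c|d are duplicates
  pm <- make_pm(scores, y)

  sel <- mrmr_rank(pm, k = 2)
  expect_equal(sel$selected[1], "a|b")  # tie with c|d broken canonically
  expect_equal(sel$selected[2], "e|f")  # duplicate excluded by redundancy

  ig <- information_gain_rank(pm, k = 1)
  expect_equal(mrmr_rank(pm, k = 1)$selected, ig$selected)

  expect_error(mrmr_rank(pm, k = 10), "exceeds")
})

test_that("MRMR greedy trace equals exhaustive evaluation of the criterion", {
  for (seed in 1:8) {
    withr::local_seed(seed)
    n <- 30
    y <- sample(rep(c("COPD", "healthy"), each = n / 2))
    scores <- matrix(rbinom(6 * n, 1, runif(6, 0.3, 0.7)), nrow = 6,
                     dimnames = list(paste0(letters[1:6], "|", letters[7:12]), NULL))
    pm <- make_pm(scores, y)
    k <- 4
    got <- mrmr_rank(pm, k = k)$selected

    # independent exhaustive greedy using the table-based MI oracle
    rel <- vapply(rownames(scores), function(p) mi_oracle(scores[p, ], y), numeric(1))
    sel <- character(0)
    remaining <- rownames(scores)
    for (step in seq_len(k)) {
      crit <- vapply(remaining, function(p) {
        if (!length(sel)) rel[[p]]
        else rel[[p]] - mean(vapply(sel, function(q) mi_oracle(scores[p, ], scores[q, ]), numeric(1)))
      }, numeric(1))
      best <- sort(remaining[crit >= max(crit) - 1e-12])[1]
      sel <- c(sel, best)
      remaining <- setdiff(remaining, best)
    }
    expect_equal(got, sel)
  }
})

test_that("Boruta confirms a planted perfect pair and stays quiet in one iteration", {
  for (seed in 1:3) {
    withr::local_seed(100 + seed)
    n <- 100
    labels <- rep(c("COPD", "healthy"), each = n / 2)
    perfect <- as.integer(labels == "COPD")
    scores <- rbind(matrix(rbinom(20 * n, 1, 0.5), nrow = 20), perfect)
    rownames(scores) <- c(paste0("a", 1:20, "|b", 1:20), "p|q")
    pm <- make_pm(scores, labels)
    b <- boruta_select(pm, max_iter = 50, seed = seed)
    expect_true("p|q" %in% b$selected)
  }

  # one iteration cannot reach binomial significance: everything tentative
  b1 <- boruta_select(pm, max_iter = 1, seed = 1)
  expect_length(b1$selected, 0)
  expect_true(all(b1$ranked$decision == "tentative"))
})

test_that("Boruta rejects zero-variance-only feature sets and tiny classes", {
  labels <- rep(c("COPD", "healthy"), each = 10)
  flat <- matrix(1L, 3, 20, dimnames = list(c("a|b", "c|d", "e|f"), NULL))
  expect_error(boruta_select(make_pm(flat, labels)), "zero variance")
  small <- make_pm(matrix(rbinom(3 * 6, 1, 0.5), 3,
                          dimnames = list(c("a|b", "c|d", "e|f"), NULL)),
                   rep(c("COPD", "healthy"), each = 3))
  expect_error(boruta_select(small), ">= 5")
})

test_that("intersect_selections takes the four-way intersection, order-invariantly", {
  mk <- function(method, sel) mirpair:::new_selection(
    method, tibble::tibble(pair = sel, score = seq_along(sel)), sel, list())
  r <- list(mk("auc", c("a|b", "c|d")), mk("infogain", "a|b"),
            mk("mrmr", c("a|b", "e|f")), mk("boruta", c("a|b", "c|d")))
  cons <- intersect_selections(r)
  expect_equal(cons$key_pairs, "a|b")
  expect_equal(cons$overlap["auc", "boruta"], 2)

  # input order does not matter
  cons2 <- intersect_selections(r[c(3, 1, 4, 2)])
  expect_equal(cons2$key_pairs, cons$key_pairs)

  # identical sets: identity
  r_same <- list(mk("auc", c("a|b", "c|d")), mk("infogain", c("a|b", "c|d")),
                 mk("mrmr", c("a|b", "c|d")), mk("boruta", c("a|b", "c|d")))
  expect_equal(intersect_selections(r_same)$key_pairs, c("a|b", "c|d"))

  # missing method
  expect_error(intersect_selections(r[1:3]), "one selection per method")
})
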