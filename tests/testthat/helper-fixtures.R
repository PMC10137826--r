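# Small in-code fixtures shared across test files.

toy_cohort <- function(values, labels, scale = "expression", id = "toy") {
  expression_cohort(values, labels, scale = scale, cohort_id = id)
}

# feature x sample matrix with names filled in
named_matrix <- function(data, n_feat, n_samp, feat_prefix = "miR-",
                         samp_prefix = "S") {
  matrix(data, nrow = n_feat,
         dimnames = list(paste0(feat_prefix, sprintf("%02d", seq_len(n_feat))),
                         paste0(samp_prefix, seq_len(n_samp))))
}

# random cohort: log-normal values, balanced labels
random_cohort <- function(n_feat = 10, n_samp = 20, seed = 1,
                          scale = "expression", digits = NULL) {
  withr::with_seed(seed, {
    v <- named_matrix(exp(rnorm(n_feat * n_samp, 6, 1)), n_feat, n_samp)
    if (!is.null(digits)) v <- round(v, digits)
    labels <- sample(rep(c("COPD", "healthy"), length.out = n_samp))
    toy_cohort(v, labels, scale = scale)
  })
}

# pair matrix direct constructor for selector tests
make_pm <- function(scores, labels) {
  stopifnot(!is.null(rownames(scores)))
  colnames(scores) <- names(labels) <- paste0("S", seq_len(ncol(scores)))
  mirpair:::new_pair_matrix(scores, labels)
}

# independent concordance-count AUC oracle (tie-aware Mann-Whitney)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "COPD"]
  neg <- scores[labels == "healthy"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# independent MI oracle in bits from a contingency table
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h(rowSums(tab) / n) + h(colSums(tab) / n) - h(as.vector(tab) / n)
}
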