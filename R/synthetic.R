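#' Generate a latent cohort with planted rank-reversal pairs
#'
#' Simulates the common biological state that two measurement platforms
#' would observe. Baseline abundances are log-normal: each feature has its
#' own log-mean (uniform over a wide abundance range) and unit log-sd,
#' independent of the diagnosis. Disease signal is planted as *within-sample
#' ordering*: for each planted pair (A, B), healthy samples show
#' `A < B` with probability `1 - p_flip` and COPD samples show `A > B` with
#' probability `1 - p_flip` (orderings enforced by swapping the two values
#' within the sample, so marginal scales are untouched). Planted pairs use
#' disjoint features, and the pair id is oriented so that the COPD-typical
#' score is 1. An optional mean-shift component (for expression-level
#' baselines) adds a log-scale shift to COPD samples in `n_shifted`
#' non-planted features.
#'
#' @param n_copd,n_healthy Sample counts per class.
#' @param n_features Total miRNA count (`2 * n_planted <= n_features`).
#' @param n_planted Number of planted rank-reversal pairs.
#' @param p_flip Per-sample probability (in [0, 0.5]) that a sample shows the
#'   opposite class's ordering.
#' @param seed Integer seed; the draw is deterministic given it.
#' @param n_shifted Number of additional features given a COPD mean shift.
#' @param shift Log-scale shift added to COPD samples in shifted features.
#' @return An object of class `mir_latent`: `values` (feature x sample
#'   abundance matrix), `labels`, `planted` (tibble of pair ids and
#'   `p_flip`), `shifted` (feature names), `seed`.
#' @export
generate_latent <- function(n_copd = 60, n_healthy = 60, n_features = 40,
                            n_planted = 5, p_flip = 0.1, seed = 1L,
                            n_shifted = 0, shift = 0) {
  stopifnot(n_copd >= 1, n_healthy >= 1, n_features >= 2,
            n_planted >= 0, 2 * n_planted <= n_features,
            p_flip >= 0, p_flip <= 0.5,
            n_shifted >= 0, 2 * n_planted + n_shifted <= n_features)
  features <- sprintf("miR-%03d", seq_len(n_features))
  samples <- c(sprintf("COPD_%03d", seq_len(n_copd)),
               sprintf("HC_%03d", seq_len(n_healthy)))
  labels <- setNames(rep(c("COPD", "healthy"), c(n_copd, n_healthy)), samples)

  withr::with_seed(seed, {
    mu <- runif(n_features, 4, 10)
    planted <- tibble::tibble(pair = character(0), p_flip = numeric(0))
    pa <- pb <- character(0)
    if (n_planted > 0) {
      # disjoint features; names are generated sorted, so a < b holds and the
      # planted pair id "a|b" is already canonical
      pa <- features[seq(1, 2 * n_planted, by = 2)]
      pb <- features[seq(2, 2 * n_planted, by = 2)]
      # members of a planted pair share a baseline log-mean so that the
      # within-sample swap leaves marginals untouched: the signal is a pure
      # rank reversal, not a mean shift
      mu[match(pb, features)] <- mu[match(pa, features)]
    }
    logv <- matrix(rnorm(n_features * length(samples), mean = mu, sd = 1),
                   nrow = n_features, dimnames = list(features, samples))

    if (n_planted > 0) {
      for (i in seq_len(n_planted)) {
        a <- pa[i]; b <- pb[i]
        for (s in samples) {
          want_a_gt_b <- if (labels[s] == "COPD") {
            runif(1) > p_flip   # COPD-typical: A > B (score 1)
          } else {
            runif(1) <= p_flip  # healthy-typical: A < B (score 0)
          }
          is_a_gt_b <- logv[a, s] > logv[b, s]
          if (want_a_gt_b != is_a_gt_b) {
            tmp <- logv[a, s]; logv[a, s] <- logv[b, s]; logv[b, s] <- tmp
          }
        }
      }
      planted <- tibble::tibble(pair = paste(pa, pb, sep = "|"),
                                p_flip = p_flip)
    }


    shifted <- character(0)
    if (n_shifted > 0) {
      shifted <- features[seq(2 * n_planted + 1, 2 * n_planted + n_shifted)]
      logv[shifted, labels == "COPD"] <-
        logv[shifted, labels == "COPD"] + shift
    }

    structure(list(values = exp(logv), labels = as_class_factor(labels),
                   planted = planted, shifted = shifted, seed = seed),
              class = "mir_latent")
  })
}

#' @export
print.mir_latent <- function(x, ...) {
  cat("<mir_latent> ", nrow(x$values), " features x ", ncol(x$values),
      " samples; ", nrow(x$planted), " planted pair(s)",
      if (length(x$shifted) > 0) paste0(", ", length(x$shifted), " shifted"),
      "\n", sep = "")
  invisible(x)
}

#' Describe a measurement platform
#'
#' A platform applies a strictly increasing transform to latent abundances,
#' adds independent technical noise, and censors its least abundant
#' measurements (detection limit). Ct-scale platforms additionally negate
#' orientation: the rendered value is a cycle count, larger = less abundant.
#'
#' @param scale `"expression"` or `"ct"`.
#' @param transform `"log_affine"` (`a * log(x) + b`), `"affine"`
#'   (`a * x + b`), or `"spline"` (a random strictly increasing monotone
#'   spline of log-abundance).
#' @param noise_sd Standard deviation of additive technical noise on the
#'   transformed scale (>= 0).
#' @param detection_limit_quantile Fraction in [0, 1): this proportion of the
#'   least abundant rendered measurements is reported missing.
#' @param a,b Transform coefficients (`a > 0`).
#' @param seed Seed for the noise draw and the spline shape.
#' @return An object of class `mir_platform`.
#' @export
platform_spec <- function(scale = c("expression", "ct"),
                          transform = c("log_affine", "affine", "spline"),
                          noise_sd = 0, detection_limit_quantile = 0,
                          a = 1, b = 0, seed = 1L) {
  scale <- check_scale(scale)
  transform <- match.arg(transform)
  stopifnot(noise_sd >= 0, detection_limit_quantile >= 0,
            detection_limit_quantile < 1, a > 0)
  structure(list(scale = scale, transform = transform, noise_sd = noise_sd,
                 detection_limit_quantile = detection_limit_quantile,
                 a = a, b = b, seed = seed),
            class = "mir_platform")
}

apply_transform <- function(spec, v) {
  switch(
    spec$transform,
    log_affine = spec$a * log(v) + spec$b,
    affine = spec$a * v + spec$b,
    spline = {
      # strictly increasing random spline of log-abundance: cumulative
      # positive increments at fixed knots, interpolated monotonically
      lv <- log(v)
      knots <- seq(min(lv) - 1e-6, max(lv) + 1e-6, length.out = 8)
      incr <- withr::with_seed(spec$seed + 7L, runif(7, 0.2, 2))
      yk <- c(0, cumsum(incr))
      f <- stats::splinefun(knots, spec$a * yk + spec$b, method = "hyman")
      matrix(f(lv), nrow = nrow(v), dimnames = dimnames(v))
    }
  )
}

#' Render a latent cohort through a platform
#'
#' Applies the platform's monotone transform, adds independent noise, flips
#' orientation for Ct-scale platforms (`rendered = offset - transformed`, so
#' larger = less abundant), and censors the least abundant fraction of
#' measurements as missing (to be resolved downstream by
#' [impute_missing()]). With zero noise and zero censoring, any two
#' renderings of the same latent cohort yield bit-identical pair matrices —
#' the invariance the pair transform is built on.
#'
#' @param latent A [generate_latent()] result.
#' @param spec A [platform_spec()].
#' @param cohort_id Identifier for the rendered cohort.
#' @return A `mir_cohort` on the platform's scale.
#' @export
render_platform <- function(latent, spec, cohort_id = "platform") {
  stopifnot(inherits(latent, "mir_latent"), inherits(spec, "mir_platform"))
  y <- apply_transform(spec, latent$values)
  if (spec$noise_sd > 0) {
    y <- y + withr::with_seed(spec$seed,
                              matrix(rnorm(length(y), sd = spec$noise_sd),
                                     nrow = nrow(y)))
  }
  if (spec$scale == "ct") {
    y <- (max(y) + 1) - y  # cycle-threshold orientation: larger = less abundant
  }
  if (spec$detection_limit_quantile > 0) {
    # censor the least abundant fraction: low values on the expression scale,
    # high values on the Ct scale
    if (spec$scale == "ct") {
      cut <- quantile(y, 1 - spec$detection_limit_quantile)
      y[y > cut] <- NA_real_
    } else {
      cut <- quantile(y, spec$detection_limit_quantile)
      y[y < cut] <- NA_real_
    }
  }
  expression_cohort(y, latent$labels, scale = spec$scale, cohort_id = cohort_id)
}

#' Simulate a two-platform study
#'
#' One latent cohort split into two disjoint sample sets, each rendered on
#' its own platform (by default a log-affine microarray-like platform and an
#' affine-negated qPCR-like Ct platform) — the structure of a two-cohort
#' cross-platform miRNA study. Sample IDs are suffixed per cohort so merges
#' are well-defined.
#'
#' @inheritParams generate_latent
#' @param specs List of two [platform_spec()]s; `NULL` for the defaults.
#' @param frac_cohort1 Fraction of samples (per class) in the first cohort.
#' @return A list with `cohorts` (two `mir_cohort`s), `latent`, and `truth`
#'   (the planted-pair tibble).
#' @export
simulate_two_platform_study <- function(n_copd = 60, n_healthy = 60,
                                        n_features = 40, n_planted = 5,
                                        p_flip = 0.1, seed = 1L, specs = NULL,
                                        frac_cohort1 = 0.5) {
  latent <- generate_latent(n_copd, n_healthy, n_features, n_planted, p_flip,
                            seed = seed)
  if (is.null(specs)) {
    specs <- list(
      platform_spec("expression", "log_affine", noise_sd = 0.1,
                    detection_limit_quantile = 0.02, a = 1.2, b = 3,
                    seed = seed + 1L),
      platform_spec("ct", "log_affine", noise_sd = 0.15,
                    detection_limit_quantile = 0.05, a = 1.44, b = 0,
                    seed = seed + 2L)
    )
  }
  stopifnot(length(specs) == 2)

  samples <- colnames(latent$values)
  labels <- latent$labels
  in1 <- withr::with_seed(seed + 3L, {
    unlist(lapply(.mirpair_classes, function(cl) {
      ids <- samples[labels == cl]
      sort(sample(ids, floor(frac_cohort1 * length(ids))))
    }), use.names = FALSE)
  })
  split_ids <- list(in1, setdiff(samples, in1))

  cohorts <- lapply(1:2, function(i) {
    sub <- latent
    sub$values <- latent$values[, split_ids[[i]], drop = FALSE]
    sub$labels <- latent$labels[split_ids[[i]]]
    co <- render_platform(sub, specs[[i]], cohort_id = paste0("platform", i))
    colnames(co$values) <- paste0(colnames(co$values), "_c", i)
    names(co$labels) <- colnames(co$values)
    co
  })
  list(cohorts = cohorts, latent = latent, truth = latent$planted,
       specs = specs)
}
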