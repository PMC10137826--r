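#' Volcano plot of a differential-expression baseline
#'
#' @param object A `mir_de` from [differential_expression()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mir_de <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$logfc, y = -log10(.data$p_value),
                               colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(thr$p), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "logFC (COPD - healthy)", y = "-log10 p",
                  colour = "flagged") +
    ggplot2::theme_minimal()
}

#' Bar chart of a selector's top-ranked pairs
#'
#' @param object A `mir_selection`.
#' @param top Number of pairs to display, default 20.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mir_selection <- function(object, top = 20, ...) {
  df <- head(object$ranked, top)
  df$pair <- factor(df$pair, levels = rev(df$pair))
  df$selected <- df$pair %in% object$selected
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$pair,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = paste0("score (", object$method, ")"), y = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve for an evaluation result
#'
#' Uses the per-sample predictions attached by [evaluate_classifier()].
#'
#' @param object A `mir_metrics` returned by [evaluate_classifier()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mir_metrics <- function(object, ...) {
  preds <- attr(object, "predictions")
  if (is.null(preds)) {
    stop("no per-sample predictions attached; plot an evaluate_classifier() result",
         call. = FALSE)
  }
  roc <- pROC::roc(response = preds$truth, predictor = preds$p_copd,
                   levels = .mirpair_classes, direction = "<", quiet = TRUE)
  df <- tibble::tibble(fpr = rev(1 - roc$specificities),
                       tpr = rev(roc$sensitivities))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc[1])) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise selector overlaps
#'
#' @param object A `mir_consensus`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mir_consensus <- function(object, ...) {
  df <- tibble::as_tibble(object$overlap, rownames = "method_a") |>
    tidyr::pivot_longer(-"method_a", names_to = "method_b", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method_a, y = .data$method_b,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared pairs") +
    ggplot2::theme_minimal()
}
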