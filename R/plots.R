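# ggplot2 views of the main result types.

#' Plot a relative-contribution result
#'
#' RC (log2 scale) against -log10 FDR q per feature, colored by direction;
#' the dashed lines mark RC = 1 and the q cutoff.
#'
#' @param object An `ehrisk_rc` table.
#' @param q_cutoff Cutoff line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ehrisk_rc <- function(object, q_cutoff = 0.05, ...) {
  dat <- dplyr::filter(object, !is.na(.data$rc), .data$rc > 0, !is.na(.data$q_fdr))
  ggplot2::ggplot(dat, ggplot2::aes(x = log2(.data$rc),
                                    y = -log10(pmax(.data$q_fdr, 1e-300)),
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(q_cutoff), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "log2 relative contribution",
                  y = "-log10 FDR q",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a model's training history
#'
#' Validation AUROC per epoch with the best epoch marked.
#'
#' @param object An `ehrisk_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ehrisk_model <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$val_auroc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "epoch", y = "validation AUROC",
                  title = paste0(object$model_kind, " training history")) +
    ggplot2::theme_minimal()
}

#' ROC curve for a fitted model on a labeled set
#'
#' @param model An `ehrisk_model`.
#' @param samples An `encoded_cohort` with both classes.
#' @return A ggplot object.
#' @export
plot_roc <- function(model, samples) {
  probs <- predict_risk(model, samples)
  ord <- order(probs, decreasing = TRUE)
  y <- samples$label[ord]
  tpr <- cumsum(y == 1L) / sum(y == 1L)
  fpr <- cumsum(y == 0L) / sum(y == 0L)
  dat <- tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s ROC (AUROC %.3f)", model$model_kind,
                                  auroc(probs, samples$label))) +
    ggplot2::theme_minimal()
}
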