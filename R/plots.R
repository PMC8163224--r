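# ggplot2 displays for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an empirical ROC curve
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcv_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = if (!is.na(object$mirna_id)) object$mirna_id else "ROC",
      subtitle = sprintf("AUC = %.3f (%d pos vs %d neg)", object$auc,
                         object$n_pos, object$n_neg)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of group-mean expression
#'
#' Tile map of mean `-delta_crt` (higher = more abundant) per miRNA and
#' group/day cell, one facet per fluid; rows follow panel order.
#'
#' @param nm A [normalize_global_mean()] table (or a
#'   [group_mean_summary()] result).
#' @return A ggplot.
#' @export
plot_group_means <- function(nm) {
  gm <- if (inherits(nm, "norm_tbl")) group_mean_summary(nm) else nm
  gm$cell <- paste(gm$group, dplyr::coalesce(gm$day, ""))
  gm$mirna_id <- factor(gm$mirna_id, levels = rev(panel_mirnas()))
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$cell, y = .data$mirna_id,
                                   fill = .data$mean_neg_delta)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~fluid) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = expression("mean -" * Delta * "Crt")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot a prediction vote table
#'
#' Tile map of the eight predictor votes per test subject, with the
#' consensus call and truth in the margin.
#'
#' @param object A [evaluate_panel()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcv_prediction <- function(object, ...) {
  vote_cols <- grep("^vote_", names(object), value = TRUE)
  long <- tidyr::pivot_longer(tidy(object),
                              cols = dplyr::all_of(vote_cols),
                              names_to = "predictor", values_to = "vote")
  long$predictor <- sub("^vote_", "", long$predictor)
  long$status <- ifelse(long$vote == "ABSTAIN", "abstain",
                        ifelse(long$vote == long$truth, "right", "wrong"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predictor,
                                     y = .data$subject_id,
                                     fill = .data$status)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(right = "#2b8cbe",
                                          wrong = "#e34a33",
                                          abstain = "grey80")) +
    ggplot2::labs(x = "Predictor", y = "Test subject", fill = "Vote") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
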