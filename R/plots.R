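#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' VIP curve with the selected elbow
#'
#' Scaled top-ranked VIP scores against rank, the chord used for elbow
#' detection, and the selected cut.
#'
#' @param object A `panel_selection` from [elbow_select()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.panel_selection <- function(object, ...) {
  elbow <- attr(object, "elbow_rank")
  m <- nrow(object)
  chord <- tibble::tibble(rank = c(1, m),
                          vip_scaled = c(object$vip_scaled[1],
                                         object$vip_scaled[m]))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank,
                                       y = .data$vip_scaled)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$selected), size = 1.2) +
    ggplot2::geom_line(data = chord, linetype = "dashed",
                       color = "firebrick") +
    ggplot2::geom_vline(xintercept = elbow, linetype = "dotted") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "steelblue",
                                           `FALSE` = "grey60"),
                                guide = "none") +
    ggplot2::labs(x = "VIP rank", y = "scaled VIP",
                  title = paste0("Panel selection: elbow at rank ", elbow)) +
    ggplot2::theme_minimal()
}

#' Distribution of training AUCs over repeated 70/30 splits
#'
#' @param object Output of [repeated_split_assessment()].
#' @param ... Unused.
#' @return A ggplot (boxplot per model family).
#' @export
autoplot.repeated_split <- function(object, ...) {
  plot_auc_distribution(object)
}

#' @rdname autoplot.repeated_split
#' @param assessment Tibble with columns `model` and `auc`.
#' @export
plot_auc_distribution <- function(assessment) {
  ggplot2::ggplot(assessment, ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "training AUC",
                  title = "Model robustness over repeated 70/30 splits") +
    ggplot2::theme_minimal()
}

#' Log2 fold-difference bar chart for a panel results table
#'
#' Bars above zero are metabolites higher in cases; significance stars mark
#' FDR-corrected p below 0.05/0.01.
#'
#' @param stats_tbl Output of [table_report()].
#' @return A ggplot.
#' @export
plot_log2fd <- function(stats_tbl) {
  df <- dplyr::mutate(
    stats_tbl,
    label = ifelse(.data$p_fdr <= 0.01, "**",
                   ifelse(.data$p_fdr <= 0.05, "*", "")),
    up = .data$log2_fd > 0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$id, .data$log2_fd), y = .data$log2_fd,
    fill = .data$up)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "steelblue"),
                               guide = "none") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "log2 fold difference (case / control)") +
    ggplot2::theme_minimal()
}

#' Pathway enrichment bubble plot
#'
#' Impact against -log10 p, point size inversely tied to p, significant
#' pathways labelled.
#'
#' @param enrichment Output of [enrichment_report()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment, ggplot2::aes(
    x = .data$impact, y = -log10(.data$p), size = -log10(.data$p),
    color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey50"),
                                guide = "none") +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(x = "pathway impact (relative betweenness of hits)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
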