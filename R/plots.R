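# ggplot2 displays for the main result types.

#' Plot a process-group frequency table
#'
#' Bar chart of the percentage of each cluster's diseases annotated with each
#' immune-system process group.
#'
#' @param object An `ivig_freq` table from [build_frequency_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ivig_freq
#' @export
autoplot.ivig_freq <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$group),
                                       y = .data$frequency_pct,
                                       fill = .data$cluster)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_discrete(labels = function(g) {
      paste0(g, "\n", PROCESS_GROUP_NAMES[g])
    }) +
    ggplot2::labs(x = "process group", y = "% of cluster diseases",
                  fill = "response cluster") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot per-cell dependence results
#'
#' Tile map of the per-cell chi-squared statistics, with significant cells
#' outlined.
#'
#' @param object An `ivig_chisq` from [test_independence()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ivig_chisq
#' @export
autoplot.ivig_chisq <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(x = factor(.data$group), y = .data$cluster,
                                      fill = .data$statistic)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = cells[cells$significant, ], shape = 8) +
    ggplot2::labs(x = "process group", y = "response cluster",
                  fill = "chi-squared") +
    ggplot2::theme_minimal()
}

#' Plot held-out score separation
#'
#' Score distributions of related and unrelated held-out pairs, with the
#' classification threshold.
#'
#' @param object An `ivig_evaluation` from [evaluate_ensemble()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ivig_evaluation
#' @export
autoplot.ivig_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$scored, ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::geom_vline(xintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = "ensemble score", y = "pairs", fill = NULL,
                  subtitle = sprintf("accuracy %.2f, AUC %.2f",
                                     object$accuracy, object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a target-by-disease score grid
#'
#' Tile map mirroring the published score-grid layout: rows are targets (or
#' functional groups), columns diseases, fill the ensemble score, label the
#' category glyph.
#'
#' @param grid Tibble from [score_grid()].
#' @return A ggplot.
#' @export
plot_score_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$disease_id, y = .data$unit,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$glyph), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal()
}

#' Plot top enriched pathways
#'
#' @param results Tibble from [enrich()].
#' @param n Number of top pathways to show.
#' @return A ggplot.
#' @export
plot_enrichment <- function(results, n = 20) {
  top <- utils::head(dplyr::arrange(results, .data$q_value), n)
  top$pathway_id <- factor(top$pathway_id, levels = rev(top$pathway_id))
  ggplot2::ggplot(top, ggplot2::aes(x = -log10(.data$q_value), y = .data$pathway_id,
                                    color = .data$significant)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k)) +
    ggplot2::labs(x = "-log10 q-value", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}
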