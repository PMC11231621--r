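#' Trajectory heatmap
#'
#' One row per nurse, one tile per interval, filled by task code; when a
#' clustering is supplied, rows are grouped by cluster and the panel is
#' faceted, which makes the block-vs-continuous charting contrast visible at
#' a glance.
#'
#' @param cohort An `rn_cohort`.
#' @param clustering Optional `rn_clustering`.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(cohort, clustering = NULL) {
  df <- cohort$trajectories |>
    dplyr::mutate(task = factor(vs_decode(cohort$task_vs, .data$code),
                                levels = cohort$task_vs$label))
  if (!is.null(clustering)) {
    df <- dplyr::left_join(df, clustering$labels, by = "nurse_id")
  }
  ord <- if (is.null(clustering)) sort(unique(df$nurse_id)) else {
    clustering$labels |>
      dplyr::arrange(.data$cluster, .data$nurse_id) |>
      dplyr::pull(.data$nurse_id)
  }
  df$nurse <- factor(df$nurse_id, levels = rev(ord))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$nurse,
                                        fill = .data$task)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_brewer(palette = "Blues") +
    ggplot2::labs(x = "interval", y = "nurse", fill = "task") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(clustering)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster),
                                 scales = "free_y", space = "free_y")
  }
  p
}

#' @rdname plot_trajectories
#' @param object An `rn_clustering`.
#' @param cohort An `rn_cohort` (required: the trajectories live there).
#' @param ... Unused.
#' @export
autoplot.rn_clustering <- function(object, cohort, ...) {
  plot_trajectories(cohort, object)
}

#' Enrichment overview plot
#'
#' Effect size against -log10(q) for every testable cluster-by-property
#' result, coloured by direction and faceted by cluster; the dashed line
#' marks q = 0.05.
#'
#' @param object An `rn_enrichment`.
#' @param alpha FDR threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rn_enrichment <- function(object, alpha = 0.05, ...) {
  df <- tidy(object) |>
    dplyr::filter(!is.na(.data$q)) |>
    dplyr::mutate(property = ifelse(is.na(.data$level), .data$element,
                                    paste0(.data$element, "=", .data$level)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = -log10(.data$q),
                                   colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$cluster), labeller = "label_both") +
    ggplot2::labs(x = "effect (in-cluster minus out-cluster)",
                  y = expression(-log[10](q))) +
    ggplot2::theme_minimal()
}

#' Cluster-conditional rate plot
#'
#' Per-cluster outcome rates with their Wilson intervals, the visual form of
#' the baseline predictor.
#'
#' @param rates Output of [cluster_conditional_rates()].
#' @param outcome Label used for the y axis.
#' @return A ggplot object.
#' @export
plot_cluster_rates <- function(rates, outcome = "outcome rate") {
  ggplot2::ggplot(rates, ggplot2::aes(x = factor(.data$cluster), y = .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::labs(x = "cluster", y = outcome) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
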