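#' Plot cluster profiles as a heatmap
#'
#' The divergent blue-red heatmap of mean normalized expression per
#' phenocluster that the cell-type rules are read from.
#'
#' @param profiles Long tibble from [profile_clusters()].
#' @return A ggplot object.
#' @export
plot_cluster_heatmap <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$marker,
                               y = factor(.data$cluster_id),
                               fill = .data$mean_expr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  name = "mean\n(normalized)") +
    ggplot2::labs(x = NULL, y = "phenocluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot infiltrate composition
#'
#' @param comp Tibble from [composition()] (optionally with `case_id` for
#'   faceting).
#' @return A ggplot object.
#' @export
plot_composition <- function(comp) {
  p <- ggplot2::ggplot(comp,
                       ggplot2::aes(x = stats::reorder(.data$cell_type,
                                                       -.data$pct),
                                    y = .data$pct)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(x = NULL, y = "% of typed infiltrate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if ("case_id" %in% names(comp)) {
    p <- p + ggplot2::facet_wrap(~case_id)
  }
  p
}

#' Plot neighbourhood enrichment and avoidance
#'
#' Tile map of the permutation test: red tiles mark significant
#' enrichment of B around A, blue tiles significant avoidance, faceted by
#' spatial range.
#'
#' @param result Tibble from [interaction_test()].
#' @return A ggplot object.
#' @export
plot_neighborhood <- function(result) {
  result$effect <- dplyr::case_when(
    result$significant_enrich ~ "enrichment",
    result$significant_avoid ~ "avoidance",
    TRUE ~ "none")
  ggplot2::ggplot(result,
                  ggplot2::aes(x = .data$type_b, y = .data$type_a,
                               fill = .data$effect)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(enrichment = "#B2182B",
                                          avoidance = "#2166AC",
                                          none = "grey95")) +
    ggplot2::facet_wrap(~range) +
    ggplot2::labs(x = "neighbour type (B)", y = "reference type (A)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
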