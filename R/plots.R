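#' Histogram of partner-preference indices
#'
#' Distribution of the directed-dyad preference indices with the chance,
#' strong-preference and avoidance thresholds marked.
#'
#' @param index_table [thompson_index()] rows (any number of group-days).
#' @param thresholds [preference_thresholds()].
#' @return A ggplot object.
#' @export
plot_preference_distribution <- function(index_table,
                                         thresholds = preference_thresholds()) {
  d <- dplyr::filter(index_table, !is.na(.data$index))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_histogram(binwidth = 0.25, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = unlist(thresholds),
                        linetype = c("dashed", "dashed", "dotted")) +
    ggplot2::labs(x = "partner-preference index",
                  y = "directed dyad-days") +
    ggplot2::theme_minimal()
}

#' Box plots of popularity per target animal
#'
#' @param pop_table [popularity()] rows for one group across days.
#' @return A ggplot object (one box per target over raters and days).
#' @export
plot_popularity <- function(pop_table) {
  ggplot2::ggplot(pop_table,
                  ggplot2::aes(x = .data$target, y = .data$pct)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::facet_wrap(~group_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "target animal", y = "% of raters' play received") +
    ggplot2::theme_minimal()
}

#' Heat map of daily play-initiation z-scores
#'
#' Animals by days, coloured by the z-score of total attacks initiated
#' relative to the group-day mean; deep colours mark animals playing
#' significantly above or below the group norm.
#'
#' @param zscores [daily_zscores()] output.
#' @return A ggplot object.
#' @export
plot_zscore_heatmap <- function(zscores) {
  ggplot2::ggplot(zscores,
                  ggplot2::aes(x = factor(.data$day), y = .data$animal_id,
                               fill = .data$z)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::facet_wrap(~group_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "day", y = "animal", fill = "z") +
    ggplot2::theme_minimal()
}

#' Plot a play network
#'
#' Deterministic circular layout; node size proportional to total attacks
#' initiated, edge width to the play proportion (directed networks) or
#' total dyadic play (undirected). Preference networks draw strong
#' preferences solid and avoidances dashed.
#'
#' @param network An igraph graph from [build_directed_network()],
#'   [build_undirected_network()] or [preference_network()].
#' @param ... Further arguments passed to [igraph::plot.igraph()].
#' @return The graph, invisibly (plots as a side effect).
#' @export
plot_network <- function(network, ...) {
  lay <- igraph::layout_in_circle(network)
  sizes <- igraph::V(network)$total_initiated
  vsize <- if (is.null(sizes)) 20 else 12 + 20 * sizes / max(sizes, 1)
  eattr <- igraph::edge_attr_names(network)
  width <- if ("weight" %in% eattr) {
    1 + 6 * igraph::E(network)$weight / max(igraph::E(network)$weight, 1e-9)
  } else 1.5
  lty <- if ("edge_class" %in% eattr) {
    ifelse(igraph::E(network)$edge_class == "solid", 1, 2)
  } else 1
  igraph::plot.igraph(network, layout = lay, vertex.size = vsize,
                      edge.width = width, edge.lty = lty,
                      vertex.color = "grey85", vertex.label.color = "black",
                      edge.arrow.size = 0.4, ...)
  invisible(network)
}

#' Bar chart of day-to-day favourite-partner rank changes
#'
#' @param changes [rank_changes()] output.
#' @return A ggplot object.
#' @export
plot_rank_changes <- function(changes) {
  long <- tidyr::pivot_longer(changes,
                              c("favorite_change", "least_favorite_change"),
                              names_to = "which", values_to = "change")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$change)) +
    ggplot2::geom_bar(fill = "grey70", colour = "grey30") +
    ggplot2::facet_wrap(~which) +
    ggplot2::labs(x = "rank change between adjacent scored days",
                  y = "animals") +
    ggplot2::theme_minimal()
}
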