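#' Directed play network for one group-day
#'
#' Nodes are animals with attribute `total_initiated` (node size in the
#' standard depiction); directed edges carry the proportion of the
#' initiator's play directed at each partner, so out-weights sum to 1 for
#' every animal that played. Proportions rather than frequencies make edge
#' weights comparable across animals that play very different amounts.
#'
#' @param counts A `play_matrix` of type `"count"`.
#' @param drop_zero Drop zero-proportion edges (default TRUE).
#' @return An igraph directed graph with vertex attribute `total_initiated`
#'   and edge attribute `weight` (proportion).
#' @export
build_directed_network <- function(counts, drop_zero = TRUE) {
  stopifnot(inherits(counts, "play_matrix"),
            attr(counts, "type") == "count")
  props <- tidy(to_proportions(counts))
  if (drop_zero) props <- dplyr::filter(props, .data$proportion > 0)
  totals <- initiated_totals(counts)
  g <- igraph::graph_from_data_frame(
    dplyr::transmute(props, from = .data$initiator, to = .data$recipient,
                     weight = .data$proportion),
    directed = TRUE,
    vertices = data.frame(name = names(totals),
                          total_initiated = as.numeric(totals)))
  igraph::graph_attr(g, "group_id") <- attr(counts, "group_id")
  igraph::graph_attr(g, "day") <- attr(counts, "day")
  g
}

#' Undirected play network (total play per dyad)
#'
#' @param counts A `play_matrix` of type `"count"`.
#' @return An igraph undirected graph; edge `weight` is
#'   `counts[i,j] + counts[j,i]` (zero-weight dyads included as weight-0
#'   edges so the dyad set stays fixed at k(k-1)/2).
#' @export
build_undirected_network <- function(counts) {
  stopifnot(inherits(counts, "play_matrix"))
  sym <- play_symmetry(counts)  # gives the dyad list
  m <- unclass_matrix(counts)
  w <- m[cbind(sym$animal_a, sym$animal_b)] +
    m[cbind(sym$animal_b, sym$animal_a)]
  totals <- initiated_totals(counts)
  g <- igraph::graph_from_data_frame(
    data.frame(from = sym$animal_a, to = sym$animal_b, weight = as.numeric(w)),
    directed = FALSE,
    vertices = data.frame(name = names(totals),
                          total_initiated = as.numeric(totals)))
  igraph::graph_attr(g, "group_id") <- attr(counts, "group_id")
  igraph::graph_attr(g, "day") <- attr(counts, "day")
  g
}

#' Preference network: only strong preferences and avoidances
#'
#' Keeps the directed dyads classified `strong_preferred` (drawn solid) or
#' `avoided` (drawn dashed), mirroring the usual depiction of significant
#' play preferences.
#'
#' @param index_table Output of [thompson_index()] (one group-day).
#' @param labels Optional node label vector; defaults to all animals in the
#'   table.
#' @return An igraph directed graph with edge attributes `index` and
#'   `edge_class` in `solid` / `dashed`.
#' @export
preference_network <- function(index_table, labels = NULL) {
  labels <- labels %||%
    sort(unique(c(index_table$initiator, index_table$recipient)))
  kept <- dplyr::filter(index_table,
                        .data$classification %in%
                          c("strong_preferred", "avoided"))
  g <- igraph::graph_from_data_frame(
    dplyr::transmute(kept, from = .data$initiator, to = .data$recipient,
                     index = .data$index,
                     edge_class = ifelse(
                       .data$classification == "strong_preferred",
                       "solid", "dashed")),
    directed = TRUE, vertices = data.frame(name = labels))
  if (nrow(index_table) > 0) {
    igraph::graph_attr(g, "group_id") <- index_table$group_id[1]
    igraph::graph_attr(g, "day") <- index_table$day[1]
  }
  g
}

#' Eigenvector centrality of a play network
#'
#' Scores each animal by the principal eigenvector of the weighted adjacency
#' matrix, normalised to a maximum of 1. Disconnected networks are scored
#' per connected component (each component's maximum is 1) and flagged.
#'
#' @param network An igraph graph (directed graphs are treated as their
#'   undirected weighted skeleton, the standard convention for play
#'   centrality).
#' @return Tibble with `animal_id`, `component`, `centrality`,
#'   `disconnected` (TRUE when the graph has more than one component with
#'   edges).
#' @export
eigenvector_centrality <- function(network) {
  g <- if (igraph::is_directed(network)) {
    igraph::as_undirected(network, mode = "collapse",
                          edge.attr.comb = list(weight = "sum", "ignore"))
  } else network
  # a dyad that never played carries no centrality information
  w0 <- igraph::E(g)$weight
  if (!is.null(w0)) g <- igraph::delete_edges(g, which(w0 == 0))
  comp <- igraph::components(g)
  disconnected <- comp$no > 1L
  out <- purrr::map_dfr(seq_len(comp$no), function(ci) {
    vs <- igraph::V(g)[comp$membership == ci]
    sub <- igraph::induced_subgraph(g, vs)
    sc <- if (igraph::ecount(sub) == 0) {
      setNames(rep(0, igraph::vcount(sub)), igraph::V(sub)$name)
    } else {
      igraph::eigen_centrality(sub, weights = igraph::E(sub)$weight)$vector
    }
    tibble::tibble(animal_id = names(sc), component = ci,
                   centrality = as.numeric(sc))
  })
  dplyr::mutate(out, disconnected = disconnected) |>
    dplyr::arrange(.data$animal_id)
}

#' Long-format edge table of a play network
#'
#' @param network An igraph graph built by this package.
#' @return Tibble with `from`, `to` and all edge attributes.
#' @export
as_edge_table <- function(network) {
  el <- igraph::as_edgelist(network)
  out <- tibble::tibble(from = el[, 1], to = el[, 2])
  for (a in igraph::edge_attr_names(network)) {
    out[[a]] <- igraph::edge_attr(network, a)
  }
  out$group_id <- igraph::graph_attr(network, "group_id") %||% NA
  out$day <- igraph::graph_attr(network, "day") %||% NA
  out
}

#' Export a play network to GraphML
#'
#' @param network An igraph graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
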