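#' Maximal cliques of a binary (thresholded) network
#'
#' Enumerates every maximal clique of the binarised network (an edge is any
#' positive weight): all-to-all connected node sets contained in no larger
#' clique. Isolated nodes are maximal 1-cliques. Enumeration is exhaustive.
#'
#' @param net A `weighted_network`, typically from [threshold_by_density()].
#' @return Tibble with one row per maximal clique: `clique` (id), `k`
#'   (node count), `nodes` (list of integer node indices), `node_ids` (list
#'   of labels).
#' @export
maximal_cliques <- function(net) {
  g <- as_igraph(net, weighted = FALSE)
  cl <- igraph::max_cliques(g, min = 1)
  nodes <- lapply(cl, function(v) sort.int(as.integer(v)))
  ord <- order(
    lengths(nodes),
    vapply(nodes, function(v) paste(v, collapse = ","), character(1))
  )
  nodes <- nodes[ord]
  tibble(
    clique = seq_along(nodes),
    k = lengths(nodes),
    nodes = nodes,
    node_ids = lapply(nodes, function(v) net$node_ids[v])
  )
}

#' Node participation in maximal k-cliques
#'
#' `P_k(v)` counts the maximal k-cliques containing node `v`; the total
#' participation `P(v)` sums over k. Satisfies
#' `sum_v P_k(v) = k * (number of maximal k-cliques)`.
#'
#' @param cliques Tibble from [maximal_cliques()].
#' @param n_nodes Total node count (nodes in no clique would otherwise be
#'   dropped; with isolated nodes counted as 1-cliques every node appears).
#' @param node_ids Optional node labels.
#' @return Tibble, one row per (node, k) with `count`, plus rows are dense
#'   in nodes: use [participation_total()] or
#'   `tidyr::pivot_wider()` for the per-node wide table.
#' @export
node_participation <- function(cliques, n_nodes,
                               node_ids = paste0("n", seq_len(n_nodes))) {
  nodes_flat <- unlist(cliques$nodes)
  if (length(nodes_flat) && max(nodes_flat) > n_nodes) {
    abort("clique contains an unknown node id")
  }
  long <- tibble(
    node = nodes_flat,
    k = rep(cliques$k, cliques$k)
  )
  ks <- sort(unique(cliques$k))
  grid <- tidyr::expand_grid(node = seq_len(n_nodes), k = ks)
  counts <- long |>
    group_by(.data$node, .data$k) |>
    summarise(count = dplyr::n(), .groups = "drop")
  out <- grid |>
    left_join(counts, by = c("node", "k")) |>
    mutate(
      count = tidyr::replace_na(.data$count, 0L),
      node_id = node_ids[.data$node]
    ) |>
    select("node", "node_id", "k", "count")
  class(out) <- c("participation_table", class(out))
  out
}

#' @rdname node_participation
#' @param table A participation table.
#' @return `participation_total()`: tibble with per-node `P` (total
#'   participation).
#' @export
participation_total <- function(table) {
  table |>
    group_by(.data$node, .data$node_id) |>
    summarise(P = sum(.data$count), .groups = "drop")
}

#' Participation aggregated by cognitive system
#'
#' Sums `P_k(v)` over the nodes of each system label. With a second table,
#' also returns the per-node difference `P_k^A(v) - P_k^B(v)` (e.g. an
#' empirical network minus a minimally wired null) aggregated the same way.
#'
#' @param table Participation table from [node_participation()].
#' @param labels Character vector mapping node index to system label (or a
#'   data frame with columns `node`, `system`); every node must be labeled.
#' @param table_b Optional second participation table on the same nodes.
#' @return Tibble with `system`, `k`, `count` (and `diff` when `table_b` is
#'   given).
#' @export
participation_by_group <- function(table, labels, table_b = NULL) {
  if (is.data.frame(labels)) {
    lab <- labels$system[order(labels$node)]
  } else {
    lab <- as.character(labels)
  }
  n <- max(table$node)
  if (length(lab) < n || anyNA(lab[seq_len(n)])) abort("unlabeled node")
  tab <- mutate(table, system = lab[.data$node])
  if (!is.null(table_b)) {
    b <- table_b |> select("node", "k", count_b = "count")
    tab <- tab |>
      left_join(b, by = c("node", "k")) |>
      mutate(count_b = tidyr::replace_na(.data$count_b, 0L))
    tab |>
      group_by(.data$system, .data$k) |>
      summarise(
        diff = sum(.data$count - .data$count_b),
        count = sum(.data$count),
        .groups = "drop"
      ) |>
      select("system", "k", "count", "diff")
  } else {
    tab |>
      group_by(.data$system, .data$k) |>
      summarise(count = sum(.data$count), .groups = "drop")
  }
}

#' Histogram of maximal clique degrees
#'
#' Distribution of maximal clique sizes, as plotted when comparing an
#' empirical network's clique spectrum against a null model's. Unimodality
#' can be assessed downstream with an established dip-test implementation.
#'
#' @param cliques Tibble from [maximal_cliques()].
#' @return Tibble with `k` and `n_cliques`.
#' @export
clique_degree_distribution <- function(cliques) {
  cliques |>
    group_by(.data$k) |>
    summarise(n_cliques = dplyr::n(), .groups = "drop")
}
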