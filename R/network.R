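#' Weighted undirected networks
#'
#' A `weighted_network` wraps a symmetric non-negative adjacency matrix with
#' zero diagonal, ordered node identifiers, and optional per-node metadata
#' (region name, 3D coordinate in arbitrary length units, cognitive-system
#' label). An edge is present exactly where the weight is positive. Node
#' strength is the row sum of the weight matrix.
#'
#' @param weights Square numeric matrix, symmetric, non-negative, zero
#'   diagonal.
#' @param node_ids Character vector of unique node labels; defaults to the
#'   matrix dimnames or `"n1"..."nN"`.
#' @param metadata Optional data frame with one row per node. Recognised
#'   columns: `id`, `name`, `x`, `y`, `z`, `system`.
#' @return An object of class `weighted_network`.
#' @examples
#' w <- matrix(c(0, 2, 0, 2, 0, 1, 0, 1, 0), 3, 3)
#' net <- weighted_network(w)
#' node_strength(net)
#' @export
weighted_network <- function(weights, node_ids = NULL, metadata = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    abort("adjacency matrix must be square")
  }
  storage.mode(weights) <- "double"
  if (anyNA(weights)) abort("adjacency matrix contains missing values")
  if (any(weights < 0)) abort("negative weights are not allowed")
  if (any(diag(weights) != 0)) abort("diagonal must be zero (no self-loops)")
  if (max(abs(weights - t(weights))) > 1e-9) {
    abort("asymmetric input: weights[i,j] must equal weights[j,i]")
  }
  # force exact symmetry so downstream comparisons are bitwise stable
  weights[lower.tri(weights)] <- t(weights)[lower.tri(weights)]
  n <- nrow(weights)
  if (is.null(node_ids)) {
    node_ids <- rownames(weights) %||% paste0("n", seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n || anyDuplicated(node_ids)) {
    abort("node_ids must be unique and match the matrix dimension")
  }
  dimnames(weights) <- list(node_ids, node_ids)
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    if (nrow(metadata) != n) {
      abort(sprintf(
        "metadata has %d rows but the network has %d nodes",
        nrow(metadata), n
      ))
    }
  }
  structure(
    list(weights = weights, node_ids = node_ids, metadata = metadata),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  ne <- n_edges(x)
  cat(sprintf(
    "<weighted_network> %d nodes, %d edges (density %.4f)\n",
    n_nodes(x), ne, ne / n_pairs(x)
  ))
  rho <- attr(x, "rho")
  if (!is.null(rho)) cat(sprintf("  thresholded at rho = %.4g\n", rho))
  if (!is.null(x$metadata)) cat("  metadata columns:",
                                paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname weighted_network
#' @param net A `weighted_network`.
#' @export
n_nodes <- function(net) length(net$node_ids)

#' @rdname weighted_network
#' @export
n_pairs <- function(net) {
  n <- n_nodes(net)
  n * (n - 1) / 2
}

#' @rdname weighted_network
#' @export
n_edges <- function(net) sum(net$weights[upper.tri(net$weights)] > 0)

#' @rdname weighted_network
#' @export
node_strength <- function(net) {
  setNames(rowSums(net$weights), net$node_ids)
}

#' Edge list of a weighted network
#'
#' @param net A `weighted_network`.
#' @return Tibble with integer node indices `i < j`, node ids `from`/`to`,
#'   and `weight`, one row per present edge.
#' @export
network_edges <- function(net) {
  w <- net$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  tibble(
    i = as.integer(idx[, 1]),
    j = as.integer(idx[, 2]),
    from = net$node_ids[idx[, 1]],
    to = net$node_ids[idx[, 2]],
    weight = w[idx]
  )
}

as_igraph <- function(net, weighted = TRUE) {
  if (weighted) {
    igraph::graph_from_adjacency_matrix(
      net$weights, mode = "undirected", weighted = TRUE, diag = FALSE
    )
  } else {
    igraph::graph_from_adjacency_matrix(
      (net$weights > 0) * 1, mode = "undirected", diag = FALSE
    )
  }
}

#' Read a weighted network from a delimited matrix file
#'
#' The file must contain a dense square numeric matrix, whitespace- or
#' comma-delimited, optionally with a header row of node ids. Asymmetry beyond
#' 1e-9 is an error (the matrix is never silently averaged). Optional node
#' metadata is read from a delimited table with columns `id`, `name`, `x`,
#' `y`, `z`, `system`; its row count must match the node count.
#'
#' @param path Path to the matrix file.
#' @param metadata_path Optional path to a node metadata table.
#' @return A [weighted_network()].
#' @export
read_network <- function(path, metadata_path = NULL) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl(",", first, fixed = TRUE)) "," else ""
  has_header <- {
    fields <- strsplit(trimws(first), if (delim == ",") "," else "[[:space:]]+")[[1]]
    suppressWarnings(anyNA(as.numeric(fields)))
  }
  raw <- utils::read.table(
    path,
    header = has_header, sep = delim,
    check.names = FALSE, row.names = NULL
  )
  m <- as.matrix(raw)
  if (!is.numeric(m)) abort("matrix file contains non-numeric entries")
  ids <- if (has_header) colnames(raw) else NULL
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- readr::read_delim(
      metadata_path,
      delim = if (grepl(",", readLines(metadata_path, n = 1L))) "," else "\t",
      show_col_types = FALSE, progress = FALSE
    )
  }
  weighted_network(m, node_ids = ids, metadata = meta)
}

#' Write a weighted network to a delimited matrix file
#'
#' Writes a dense CSV with a header row of node ids (full precision, so a
#' read/write round trip is exact). When the network carries a density
#' threshold attribute, a sidecar `<path>.info` records `rho` and the
#' retained-edge count.
#'
#' @param net A `weighted_network`.
#' @param path Output path.
#' @param metadata_path Optional path to also write the node metadata table.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, metadata_path = NULL) {
  df <- as.data.frame(net$weights, check.names = FALSE)
  readr::write_csv(df, path, progress = FALSE)
  rho <- attr(net, "rho")
  if (!is.null(rho)) {
    writeLines(
      c(sprintf("rho = %.17g", rho),
        sprintf("retained_edges = %d", n_edges(net))),
      paste0(path, ".info")
    )
  }
  if (!is.null(metadata_path) && !is.null(net$metadata)) {
    readr::write_csv(net$metadata, metadata_path, progress = FALSE)
  }
  invisible(path)
}

#' Threshold a network at a target edge density
#'
#' Retains exactly `floor(rho * n(n-1)/2)` highest-weight edges; all other
#' weights are set to zero. The density denominator is the count of all
#' unordered node pairs, including pairs that never had an edge. An exact tie
#' in weight at the cut boundary is an error unless ties are first broken
#' (see [add_tiebreak_noise()]); a deterministic lexicographic tie-break can
#' be requested instead.
#'
#' @param net A `weighted_network`.
#' @param rho Target edge density in `[0, 1]`.
#' @param ties `"error"` (default) errors on a tie crossing the cut;
#'   `"lexicographic"` breaks ties by node-pair order.
#' @return A `weighted_network` with attributes `rho` and `retained_edges`.
#' @export
threshold_by_density <- function(net, rho, ties = c("error", "lexicographic")) {
  ties <- match.arg(ties)
  stopifnot(is.numeric(rho), length(rho) == 1, rho >= 0, rho <= 1)
  keep_n <- floor(rho * n_pairs(net))
  ed <- network_edges(net)
  ed <- ed[order(-ed$weight, ed$i, ed$j), ]
  keep_n <- min(keep_n, nrow(ed))
  if (ties == "error" && keep_n > 0 && keep_n < nrow(ed) &&
      ed$weight[keep_n] == ed$weight[keep_n + 1]) {
    abort(paste0(
      "tie at the density cut (weight ", ed$weight[keep_n],
      "); break ties first with add_tiebreak_noise() or ties = \"lexicographic\""
    ))
  }
  w <- matrix(0, n_nodes(net), n_nodes(net))
  if (keep_n > 0) {
    sel <- ed[seq_len(keep_n), ]
    w[cbind(sel$i, sel$j)] <- sel$weight
    w[cbind(sel$j, sel$i)] <- sel$weight
  }
  out <- weighted_network(w, net$node_ids, net$metadata)
  attr(out, "rho") <- rho
  attr(out, "retained_edges") <- keep_n
  out
}

#' Break tied edge weights with bounded uniform noise
#'
#' Adds an independent uniform draw from `[0, epsilon]` to every positive
#' weight (symmetrically), making positive weights pairwise distinct with
#' probability 1 while perturbing the filtration order only among former
#' ties. Deterministic given `seed`.
#'
#' @param net A `weighted_network`.
#' @param epsilon Upper bound of the noise, default `1e-4`. Must be positive.
#' @param seed Integer seed.
#' @return A `weighted_network` with perturbed weights.
#' @export
add_tiebreak_noise <- function(net, epsilon = 1e-4, seed = 1L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("epsilon must be a single positive number")
  }
  w <- net$weights
  up <- which(upper.tri(w) & w > 0)
  withr_seed(seed, {
    noise <- runif(length(up), 0, epsilon)
  })
  w[up] <- w[up] + noise
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  weighted_network(w, net$node_ids, net$metadata)
}

# run code under a temporary RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Element-wise group average of networks
#'
#' Arithmetic mean of the weight matrices over a list of networks on the same
#' ordered node set; absent edges contribute zeros to the mean, so an edge
#' present in a subset of networks is down-weighted accordingly.
#'
#' @param nets List of `weighted_network` objects with identical node ids.
#' @return A `weighted_network` (metadata from the first network).
#' @export
group_average <- function(nets) {
  stopifnot(length(nets) >= 1)
  ids <- nets[[1]]$node_ids
  for (k in seq_along(nets)) {
    if (!identical(nets[[k]]$node_ids, ids)) {
      abort(sprintf("network %d has a different node set/order", k))
    }
  }
  w <- Reduce(`+`, lapply(nets, `[[`, "weights")) / length(nets)
  weighted_network(w, ids, nets[[1]]$metadata)
}
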