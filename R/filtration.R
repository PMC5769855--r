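#' Weight rank clique filtration of a weighted network
#'
#' Orders the present edges by strictly decreasing weight, defining the
#' nested sequence of binary graphs `G_0 (empty) < G_1 < ... < G_|E|` in
#' which `G_i` contains the `i` heaviest edges. Each step is indexed by its
#' edge density `rho_i = i / (n(n-1)/2)` over all unordered node pairs.
#' Absent edges are never added, so density tops out at the network's own
#' density.
#'
#' @param net A `weighted_network`.
#' @param ties `"lexicographic"` (default) breaks equal weights
#'   deterministically by node-pair order; `"error"` insists on pairwise
#'   distinct positive weights (use [add_tiebreak_noise()] first).
#' @return A `wrc_filtration`: node count, node ids, and an `edges` tibble
#'   (`step`, `i`, `j`, `weight`, `rho`) in filtration order.
#' @export
build_filtration <- function(net, ties = c("lexicographic", "error")) {
  ties <- match.arg(ties)
  ed <- network_edges(net)
  if (ties == "error" && anyDuplicated(ed$weight)) {
    abort("duplicate edge weights; add_tiebreak_noise() or ties = \"lexicographic\"")
  }
  ed <- ed[order(-ed$weight, ed$i, ed$j), ]
  np <- n_pairs(net)
  ed$step <- seq_len(nrow(ed))
  ed$rho <- ed$step / np
  structure(
    list(
      n_nodes = n_nodes(net),
      node_ids = net$node_ids,
      n_pairs = np,
      edges = as_tibble(ed[, c("step", "i", "j", "from", "to", "weight", "rho")])
    ),
    class = "wrc_filtration"
  )
}

#' @export
print.wrc_filtration <- function(x, ...) {
  cat(sprintf(
    "<wrc_filtration> %d nodes, %d steps, final density %.4f\n",
    x$n_nodes, nrow(x$edges),
    if (nrow(x$edges)) max(x$edges$rho) else 0
  ))
  invisible(x)
}

simplex_key <- function(M) {
  apply(M, 1L, paste, collapse = ",")
}

#' Flag (clique) complex of a filtration
#'
#' Enumerates all cliques of the final graph with up to `max_dim + 2` nodes
#' (simplices of dimension up to `max_dim + 1`) and stamps each with the
#' filtration step at which it completes — the latest of its edges' steps.
#' Simplices of each dimension are stored in (step, lexicographic) order, so
#' the complex at step `s` is a prefix of each dimension's list; every face
#' of a stored simplex carries an earlier-or-equal stamp.
#'
#' @param filt A `wrc_filtration`.
#' @param max_dim Maximum homology dimension of interest (default 2);
#'   simplices one dimension higher are enumerated to detect deaths.
#' @return A `flag_complex`: per-dimension simplex matrices `simp`, stamps
#'   `step`, and boundary columns `bnd` (positions into the next-lower
#'   dimension's list).
#' @export
flag_complex <- function(filt, max_dim = 2) {
  stopifnot(inherits(filt, "wrc_filtration"), max_dim >= 1)
  n <- filt$n_nodes
  ed <- filt$edges
  top <- max_dim + 1L
  simp <- vector("list", top)
  step <- vector("list", top)
  bnd <- vector("list", top)
  simp[[1]] <- cbind(ed$i, ed$j)
  step[[1]] <- ed$step
  estep <- matrix(NA_integer_, n, n)
  if (nrow(ed)) {
    estep[cbind(ed$i, ed$j)] <- ed$step
    estep[cbind(ed$j, ed$i)] <- ed$step
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(ed)) g <- igraph::add_edges(g, rbind(ed$i, ed$j))
  for (d in seq(2L, top)) {
    size <- d + 1L
    cl <- igraph::cliques(g, min = size, max = size)
    if (!length(cl)) {
      simp[[d]] <- matrix(integer(0), 0, size)
      step[[d]] <- integer(0)
      bnd[[d]] <- list()
      next
    }
    M <- t(vapply(cl, function(v) sort.int(as.integer(v)), integer(size)))
    pr <- combn(size, 2)
    st <- rep(0L, nrow(M))
    for (c_ in seq_len(ncol(pr))) {
      st <- pmax(st, estep[cbind(M[, pr[1, c_]], M[, pr[2, c_]])])
    }
    ord <- do.call(order, c(list(st), lapply(seq_len(size), function(c_) M[, c_])))
    M <- M[ord, , drop = FALSE]
    st <- st[ord]
    prev_key <- simplex_key(simp[[d - 1L]])
    face_pos <- matrix(0L, nrow(M), size)
    for (p in seq_len(size)) {
      face_pos[, p] <- match(simplex_key(M[, -p, drop = FALSE]), prev_key)
    }
    if (anyNA(face_pos)) abort("internal: face of a clique missing from the complex")
    simp[[d]] <- M
    step[[d]] <- st
    bnd[[d]] <- lapply(seq_len(nrow(M)), function(r) sort.int(face_pos[r, ]))
  }
  structure(
    list(
      n_nodes = n, node_ids = filt$node_ids, n_pairs = filt$n_pairs,
      max_dim = max_dim, simp = simp, step = step, bnd = bnd
    ),
    class = "flag_complex"
  )
}

#' @export
print.flag_complex <- function(x, ...) {
  cat("<flag_complex>",
      paste(sprintf("dim %d: %d", seq_along(x$simp), vapply(x$simp, nrow, 0L)),
            collapse = ", "),
      "\n")
  invisible(x)
}

# number of simplices of each dimension present at a step (stamps ascending)
slice_counts <- function(fc, at_step) {
  vapply(fc$step, function(st) findInterval(at_step, st), 0L)
}
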