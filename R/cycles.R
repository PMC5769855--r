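#' Flag-complex slice at a filtration step
#'
#' The clique complex of the binary graph at one filtration step, used as
#' the ambient complex for cycle equivalence and boundingness tests.
#'
#' @param filt A `wrc_filtration`.
#' @param step Filtration step (0 to `|E|`).
#' @param max_dim Maximum homology dimension of interest.
#' @return A `flag_slice` object.
#' @export
flag_slice <- function(filt, step, max_dim = 2) {
  stopifnot(inherits(filt, "wrc_filtration"))
  if (step < 0 || step > nrow(filt$edges)) abort("step out of range")
  structure(
    list(fc = flag_complex(filt, max_dim), step = as.integer(step)),
    class = "flag_slice"
  )
}

# positions (in fc$simp[[k]]) of the rows of a clique matrix; errors if a
# clique is absent from the slice
chain_positions <- function(cliques, fc, k, at_step) {
  M <- matrix(as.integer(cliques), ncol = k + 1L)
  M <- t(apply(M, 1L, sort.int))
  pos <- match(simplex_key(M), simplex_key(fc$simp[[k]]))
  if (anyNA(pos)) abort("cycle uses a clique absent from the complex")
  if (any(fc$step[[k]][pos] > at_step)) {
    abort("cycle uses a clique not yet present at this slice")
  }
  sort.int(pos)
}

# is the Z2 chain (positions of k-simplices) a boundary at the slice?
chain_is_bounding <- function(chain, fc, k, at_step) {
  if (!length(chain)) return(TRUE)
  n_up <- findInterval(at_step, fc$step[[k + 1L]])
  gf2_in_span(fc$bnd[[k + 1L]][seq_len(n_up)], chain, nrow(fc$simp[[k]]))
}

# is the chain closed (boundary zero)?
chain_is_closed <- function(chain, fc, k) {
  if (k == 1L) {
    faces <- c(fc$simp[[1L]][chain, , drop = FALSE])
  } else {
    faces <- unlist(fc$bnd[[k]][chain])
  }
  all(table(faces) %% 2 == 0)
}

rep_tibble <- function(dimension, cliques, birth_step, class_id = NA_integer_,
                       cycle_nodes = NULL) {
  nodes <- sort.int(unique(as.integer(cliques)))
  tibble(
    dimension = dimension,
    n_nodes = length(nodes),
    nodes = list(nodes),
    cliques = list(cliques),
    cycle_nodes = list(cycle_nodes %||% nodes),
    birth_step = birth_step,
    class_id = class_id
  )
}

#' Are two cycles Z2-equivalent in a complex slice?
#'
#' Two k-cycles are equivalent when their symmetric difference is a boundary
#' of (k+2)-node cliques of the slice; a cycle is trivial when equivalent to
#' the empty cycle. Both cycles must be supported on cliques present in the
#' slice.
#'
#' @param z1,z2 Cycle representatives: rows of the tibble returned by
#'   [minimal_1cycles()]/[minimal_2cycles()], or plain matrices with one
#'   (k+1)-node clique per row. `z2` may be `NULL` for a triviality test.
#' @param slice A [flag_slice()].
#' @param dimension Cycle dimension, required when passing plain matrices.
#' @return Logical.
#' @export
cycles_equivalent <- function(z1, z2, slice, dimension = NULL) {
  stopifnot(inherits(slice, "flag_slice"))
  get_chain <- function(z) {
    if (is.null(z)) return(list(k = NULL, m = NULL))
    if (is.data.frame(z)) {
      stopifnot(nrow(z) == 1)
      list(k = z$dimension[[1]], m = z$cliques[[1]])
    } else {
      list(k = dimension, m = z)
    }
  }
  c1 <- get_chain(z1)
  c2 <- get_chain(z2)
  k <- c1$k %||% c2$k %||% dimension
  if (is.null(k)) abort("dimension must be supplied for matrix input")
  fc <- slice$fc
  p1 <- chain_positions(c1$m, fc, k, slice$step)
  p2 <- if (is.null(c2$m)) integer(0) else chain_positions(c2$m, fc, k, slice$step)
  diffchain <- gf2_xor(p1, p2)
  for (ch in list(p1, p2)) {
    if (length(ch) && !chain_is_closed(ch, fc, k)) {
      abort("input is not a closed cycle")
    }
  }
  chain_is_bounding(diffchain, fc, k, slice$step)
}

# assign equivalence-class ids to a list of chains at a slice
classify_chains <- function(chains, fc, k, at_step) {
  ids <- integer(length(chains))
  reps <- list()
  for (ii in seq_along(chains)) {
    assigned <- FALSE
    for (cc in seq_along(reps)) {
      if (chain_is_bounding(gf2_xor(chains[[ii]], reps[[cc]]), fc, k, at_step)) {
        ids[ii] <- cc
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps[[length(reps) + 1L]] <- chains[[ii]]
      ids[ii] <- length(reps)
    }
  }
  ids
}

#' Minimal 1-cycle representatives of a persistence class
#'
#' Recovers every minimum-node representative of a dimension-1 class at its
#' birth density: the network is thresholded at the step immediately
#' preceding birth, a breadth-first search finds all minimum-length paths
#' between the endpoints of the birth edge, and each path closed by the
#' birth edge is kept after verifying it is closed and non-bounding at the
#' birth slice. Representatives arising from different equivalence classes
#' are all returned, tagged with a class id.
#'
#' @param filt A `wrc_filtration`.
#' @param point One row of a [persistent_homology()] diagram with
#'   `dimension == 1`.
#' @param cap Maximum number of representatives before erroring (guards
#'   pathological inputs; hitting the cap is an error, not a truncation).
#' @return Tibble of representatives: `dimension`, `n_nodes`, `nodes`,
#'   `cliques` (edge matrix), `cycle_nodes` (node sequence around the
#'   cycle), `birth_step`, `class_id`.
#' @export
minimal_1cycles <- function(filt, point, cap = 100L) {
  stopifnot(inherits(filt, "wrc_filtration"), nrow(point) == 1,
            point$dimension[[1]] == 1)
  b_step <- point$birth_step[[1]]
  be <- point$birth_simplex[[1]]
  prev <- filt$edges[filt$edges$step < b_step, ]
  g <- igraph::make_empty_graph(filt$n_nodes, directed = FALSE)
  if (nrow(prev)) g <- igraph::add_edges(g, rbind(prev$i, prev$j))
  sp <- igraph::all_shortest_paths(g, from = be[1], to = be[2])
  paths <- sp$vpaths %||% sp$res
  if (!length(paths)) {
    abort("internal: birth-edge endpoints disconnected before the birth step")
  }
  if (length(paths) > cap) {
    abort(sprintf("representative count exceeds cap (%d)", cap))
  }
  fc <- flag_complex(filt, max_dim = 2)
  out <- list()
  chains <- list()
  for (p in paths) {
    seqn <- as.integer(p)
    edges <- cbind(seqn[-length(seqn)], seqn[-1])
    edges <- rbind(edges, be)
    edges <- t(apply(edges, 1, sort.int))
    chain <- chain_positions(edges, fc, 1L, b_step)
    if (!chain_is_closed(chain, fc, 1L)) next
    if (chain_is_bounding(chain, fc, 1L, b_step)) next
    chains[[length(chains) + 1L]] <- chain
    out[[length(out) + 1L]] <- rep_tibble(
      1L, edges, b_step,
      cycle_nodes = seqn
    )
  }
  if (!length(out)) {
    abort("internal: no non-bounding representative found at birth")
  }
  res <- bind_rows(out)
  res$class_id <- classify_chains(chains, fc, 1L, b_step)
  res
}

#' Minimal 2-cycle representatives of a persistence class
#'
#' Exhaustive search, by increasing node count up to `node_cap`, over node
#' subsets containing the birth triangle: within each subset, all Z2 sums of
#' slice triangles that contain the birth triangle, are closed, use every
#' node of the subset, and are non-bounding at the birth slice. All
#' minimum-node solutions are returned. Exceeding `node_cap` without a
#' certificate is a diagnostic failure, never a silent truncation.
#'
#' @param filt A `wrc_filtration`.
#' @param point One row of a diagram with `dimension == 2`.
#' @param node_cap Largest subset size searched (default 12).
#' @param cap Maximum representatives before erroring.
#' @return Tibble of representatives as in [minimal_1cycles()]; `cliques`
#'   holds the triangle matrix.
#' @export
minimal_2cycles <- function(filt, point, node_cap = 12L, cap = 100L) {
  stopifnot(inherits(filt, "wrc_filtration"), nrow(point) == 1,
            point$dimension[[1]] == 2)
  b_step <- point$birth_step[[1]]
  bt <- sort.int(point$birth_simplex[[1]])
  fc <- flag_complex(filt, max_dim = 2)
  n_tri <- findInterval(b_step, fc$step[[2]])
  tri <- fc$simp[[2]][seq_len(n_tri), , drop = FALSE]
  pool <- sort.int(unique(as.integer(tri)))
  extra <- setdiff(pool, bt)
  found <- list()
  chains <- list()
  for (size in seq(3L, min(node_cap, length(pool)))) {
    pick <- size - 3L
    subsets <- if (pick == 0L) {
      list(integer(0))
    } else if (length(extra) < pick) {
      list()
    } else {
      asplit(combn(extra, pick), 2)
    }
    for (ss in seq_along(subsets)) {
      S <- sort.int(c(bt, subsets[[ss]]))
      inS <- which(rowSums(matrix(tri %in% S, nrow = n_tri)) == 3L)
      if (!length(inS)) next
      birth_local <- which(vapply(
        inS, function(r) all(tri[r, ] == bt), logical(1)
      ))
      if (!length(birth_local)) next
      cols <- fc$bnd[[2]][inS]
      basis <- gf2_nullspace(cols, nrow(fc$simp[[1]]))
      if (!length(basis)) next
      has_b <- vapply(basis, function(v) birth_local %in% v, logical(1))
      if (!any(has_b)) next
      part <- basis[[which(has_b)[1]]]
      rest <- basis[-which(has_b)[1]]
      rest <- lapply(rest, function(v) {
        if (birth_local %in% v) gf2_xor(v, part) else v
      })
      if (length(rest) > 12L) {
        abort("2-cycle search space too large; raise node_cap or simplify the fixture")
      }
      for (mask in seq_len(2^length(rest)) - 1L) {
        sol <- part
        mm <- mask
        idx <- 1L
        while (mm > 0L) {
          if (mm %% 2L == 1L) sol <- gf2_xor(sol, rest[[idx]])
          mm <- mm %/% 2L
          idx <- idx + 1L
        }
        tri_sel <- inS[sol]
        used <- sort.int(unique(as.integer(tri[tri_sel, , drop = FALSE])))
        if (!identical(used, S)) next
        chain <- sort.int(tri_sel)
        if (chain_is_bounding(chain, fc, 2L, b_step)) next
        key <- paste(chain, collapse = ",")
        if (key %in% names(chains)) next
        chains[[key]] <- chain
        found[[key]] <- rep_tibble(
          2L, fc$simp[[2]][chain, , drop = FALSE], b_step
        )
        if (length(found) > cap) {
          abort(sprintf("representative count exceeds cap (%d)", cap))
        }
      }
    }
    if (length(found)) break
  }
  if (!length(found)) {
    abort(sprintf(
      "no closed non-bounding 2-cycle found within node_cap = %d; raise node_cap",
      node_cap
    ))
  }
  res <- bind_rows(found)
  res$class_id <- classify_chains(unname(chains), fc, 2L, b_step)
  res
}
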