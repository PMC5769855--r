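#' Minimally wired null network from node coordinates
#'
#' Builds the complete weighted network on a set of 3D node coordinates with
#' edge weight equal to the inverse Euclidean distance between the endpoints,
#' `w_ij = 1/d(i,j)`. This is the wiring-cost-minimising spatial null model:
#' physically close nodes get the strongest edges. The caller typically
#' thresholds the result at the empirical density (e.g. 0.25) with
#' [threshold_by_density()]. Only relative distances matter under the
#' edge-rank filtration, so coordinate units are arbitrary.
#'
#' @param coords Numeric matrix, n x 3 (or n x d), one row per node; no two
#'   rows may coincide.
#' @param node_ids Optional node labels.
#' @return A `weighted_network`; the coordinates are attached as metadata
#'   columns `x`, `y`, `z` when 3D.
#' @export
minimally_wired <- function(coords, node_ids = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) abort("need at least two points")
  d <- as.matrix(stats::dist(coords))
  off <- d[upper.tri(d)]
  if (any(off == 0)) abort("coincident points: pairwise distances must be positive")
  w <- 1 / d
  diag(w) <- 0
  meta <- NULL
  if (ncol(coords) == 3) {
    meta <- tibble(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  }
  weighted_network(w, node_ids, meta)
}

#' Random geometric network in the unit cube
#'
#' Samples `n` i.i.d. uniform points in the unit cube and returns the
#' minimally wired (inverse-distance) complete network on them. With
#' probability 1 all `n(n-1)/2` weights are distinct. Deterministic given
#' `seed`.
#'
#' @param n Number of nodes (>= 2).
#' @param seed Integer seed.
#' @param dim Dimension of the box, default 3.
#' @return List with elements `coords` (n x dim matrix) and `network`.
#' @export
random_geometric_network <- function(n, seed = 1L, dim = 3L) {
  stopifnot(n >= 2)
  coords <- withr_seed(seed, {
    matrix(runif(n * dim), nrow = n, ncol = dim)
  })
  list(coords = coords, network = minimally_wired(coords))
}

#' Specification of a planted topological cavity
#'
#' Describes a closed k-cycle "shell" (a list of (k+1)-node cliques whose
#' k-faces each occur an even number of times), the total node count, the
#' target positions of birth and death in the descending-weight edge
#' ordering, and the fill edges whose arrival kills the cavity. Used by
#' [planted_cavity_network()] to build networks with exactly known
#' persistence.
#'
#' @param shell List of integer vectors, each a (k+1)-node clique (edges for
#'   a 1-cycle, triangles for a 2-cycle).
#' @param n_nodes Total nodes in the network (>= nodes used by the shell).
#' @param fill_edges Two-column matrix (or list of pairs) of edges that kill
#'   the cavity, added after the shell.
#' @param target_birth_index Position of the shell-completing edge in the
#'   edge ordering; must equal the shell's edge count.
#' @param target_death_index Position of the killing fill edge; must exceed
#'   `target_birth_index`.
#' @param death_at_fill Which fill edge (in the given order) kills the
#'   cavity; earlier fill edges may shrink the representative without killing
#'   the class (e.g. chords of a pentagon). Default 1.
#' @return A `planted_cavity_spec` list.
#' @export
planted_cavity_spec <- function(shell, n_nodes, fill_edges,
                                target_birth_index = NULL,
                                target_death_index = NULL,
                                death_at_fill = 1L) {
  shell <- lapply(shell, function(s) sort(as.integer(s)))
  k <- length(shell[[1]]) - 1L
  if (!all(lengths(shell) == k + 1L)) {
    abort("all shell cliques must have the same size")
  }
  if (!k %in% 1:2) abort("shell must be a 1-cycle (edges) or 2-cycle (triangles)")
  # closedness: every (k-1)-face appears an even number of times
  faces <- unlist(lapply(shell, function(s) {
    apply(combn(s, k), 2, paste, collapse = "-")
  }))
  if (any(table(faces) %% 2 != 0)) {
    abort("shell is not closed: some face appears an odd number of times")
  }
  fe <- if (is.matrix(fill_edges)) fill_edges else do.call(rbind, fill_edges)
  fe <- t(apply(matrix(as.integer(fe), ncol = 2), 1, sort))
  shell_edges <- unique(do.call(rbind, lapply(shell, function(s) {
    t(combn(s, 2))
  })))
  shell_edges <- shell_edges[order(shell_edges[, 1], shell_edges[, 2]), ,
                             drop = FALSE]
  s_count <- nrow(shell_edges)
  death_at_fill <- as.integer(death_at_fill)
  stopifnot(death_at_fill >= 1, death_at_fill <= nrow(fe))
  target_birth_index <- target_birth_index %||% s_count
  target_death_index <- target_death_index %||% (s_count + death_at_fill)
  if (target_birth_index != s_count) {
    abort(sprintf(
      "target_birth_index must equal the shell edge count (%d)", s_count
    ))
  }
  if (target_death_index <= target_birth_index + death_at_fill - 1L) {
    abort("shell bounded before completion: a fill edge is ranked above a shell edge")
  }
  used <- max(c(unlist(shell), fe))
  if (n_nodes < used) abort("n_nodes smaller than the largest node used")
  structure(
    list(
      dimension = k, shell = shell, shell_edges = shell_edges,
      n_nodes = as.integer(n_nodes), fill_edges = fe,
      death_at_fill = death_at_fill,
      target_birth_index = as.integer(target_birth_index),
      target_death_index = as.integer(target_death_index)
    ),
    class = "planted_cavity_spec"
  )
}

#' Network with a planted topological cavity and exact ground truth
#'
#' Assigns strictly decreasing integer weights by explicit rank so the
#' shell's final edge arrives exactly at `target_birth_index` and the first
#' fill edge at `target_death_index`. Any gap between birth and death is
#' padded with edges among spare nodes disjoint from the shell (which cannot
#' bound it). Ground-truth densities are `index / (n(n-1)/2)` and are exact
#' by construction.
#'
#' @param spec A [planted_cavity_spec()].
#' @return List with `network` (a `weighted_network`), `dimension`,
#'   `rho_birth`, `rho_death`, `birth_index`, `death_index`.
#' @export
planted_cavity_network <- function(spec) {
  stopifnot(inherits(spec, "planted_cavity_spec"))
  n <- spec$n_nodes
  pairs <- n * (n - 1) / 2
  first_fill <- spec$target_death_index - (spec$death_at_fill - 1L)
  gap <- first_fill - spec$target_birth_index - 1L
  edges <- spec$shell_edges
  if (gap > 0) {
    shell_nodes <- sort(unique(unlist(spec$shell)))
    spare <- setdiff(seq_len(n), shell_nodes)
    if (length(spare) < 2 || choose(length(spare), 2) < gap) {
      abort("not enough spare nodes to pad between birth and death indices")
    }
    pad <- t(combn(spare, 2))[seq_len(gap), , drop = FALSE]
    edges <- rbind(edges, pad)
  }
  edges <- rbind(edges, spec$fill_edges)
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
    abort("fill edges overlap shell or pad edges")
  }
  w <- matrix(0, n, n)
  rank_w <- rev(seq_len(nrow(edges)))  # descending integers, rank 1 heaviest
  w[edges] <- rank_w
  w[edges[, c(2, 1), drop = FALSE]] <- rank_w
  list(
    network = weighted_network(w),
    dimension = spec$dimension,
    rho_birth = spec$target_birth_index / pairs,
    rho_death = spec$target_death_index / pairs,
    birth_index = spec$target_birth_index,
    death_index = spec$target_death_index
  )
}

#' Ready-made planted fixtures
#'
#' `planted_square()`: a 4-node square shell (4 edges) plus one chord, giving
#' one 1-dimensional cavity with `rho_birth = 4/6`, `rho_death = 5/6`.
#' `planted_pentagon()`: a 5-node pentagon whose cavity is shrunk by a first
#' chord and killed by a second, `rho_birth = 5/10`, `rho_death = 7/10`.
#' `planted_octahedron()`: the octahedral 2-sphere (6 nodes, 12 edges,
#' 8 triangles) plus one antipodal diagonal, giving one 2-dimensional cavity
#' with `rho_birth = 12/15`, `rho_death = 13/15`.
#'
#' @return As [planted_cavity_network()].
#' @export
planted_square <- function() {
  spec <- planted_cavity_spec(
    shell = list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)),
    n_nodes = 4,
    fill_edges = rbind(c(1, 3))
  )
  planted_cavity_network(spec)
}

#' @rdname planted_square
#' @export
planted_pentagon <- function() {
  spec <- planted_cavity_spec(
    shell = list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5)),
    n_nodes = 5,
    fill_edges = rbind(c(1, 3), c(1, 4)),
    death_at_fill = 2
  )
  planted_cavity_network(spec)
}

#' @rdname planted_square
#' @export
planted_octahedron <- function() {
  # antipodal pairs: (1,6), (2,4), (3,5); faces avoid all three
  faces <- list(
    c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 2, 5),
    c(6, 2, 3), c(6, 3, 4), c(6, 4, 5), c(6, 2, 5)
  )
  spec <- planted_cavity_spec(
    shell = faces,
    n_nodes = 6,
    fill_edges = rbind(c(1, 6))
  )
  planted_cavity_network(spec)
}

#' Perturbed repeat "scans" of a template network
#'
#' Emulates an ensemble of repeated measurements of one underlying network:
#' each scan applies independent multiplicative log-normal jitter to the
#' weights (log-sd `weight_jitter`) and flips a Bernoulli(`edge_flip_rate`)
#' random subset of edges — deleted edges are removed, and an equal number of
#' absent pairs are inserted with weak weights (below the template minimum).
#' Deterministic given `seed`.
#'
#' @param template A `weighted_network`.
#' @param n_scans Number of scans.
#' @param weight_jitter Log-normal sigma for weight noise (0 disables).
#' @param edge_flip_rate Per-edge deletion probability in `[0, 1)`; matched
#'   insertions keep the expected edge count.
#' @param seed Integer seed.
#' @return List of `weighted_network` scans.
#' @export
perturb_scans <- function(template, n_scans, weight_jitter = 0.05,
                          edge_flip_rate = 0, seed = 1L) {
  stopifnot(
    n_scans >= 1,
    weight_jitter >= 0,
    edge_flip_rate >= 0, edge_flip_rate < 1
  )
  n <- n_nodes(template)
  withr_seed(seed, {
    lapply(seq_len(n_scans), function(s) {
      w <- template$weights
      up <- which(upper.tri(w) & w > 0)
      if (weight_jitter > 0 && length(up)) {
        w[up] <- w[up] * exp(rnorm(length(up), 0, weight_jitter))
      }
      if (edge_flip_rate > 0 && length(up)) {
        del <- up[runif(length(up)) < edge_flip_rate]
        absent <- which(upper.tri(w) & w == 0)
        ins <- if (length(absent)) {
          sample(absent, min(length(del), length(absent)))
        } else {
          integer(0)
        }
        wmin <- min(w[up])
        w[del] <- 0
        if (length(ins)) w[ins] <- runif(length(ins), 0, wmin / 2)
      }
      w[lower.tri(w)] <- t(w)[lower.tri(w)]
      weighted_network(w, template$node_ids, template$metadata)
    })
  })
}
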