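#' Induced subnetwork on a node subset
#'
#' @param net A `weighted_network`.
#' @param nodes Integer node indices (or node id labels).
#' @return A `weighted_network` on the subset, in the given order.
#' @export
induced_network <- function(net, nodes) {
  if (is.character(nodes)) nodes <- match(nodes, net$node_ids)
  stopifnot(!anyNA(nodes))
  weighted_network(
    net$weights[nodes, nodes, drop = FALSE],
    net$node_ids[nodes],
    if (!is.null(net$metadata)) net$metadata[nodes, ]
  )
}

#' Rule 1: do the reference-cycle nodes surround a cavity in a scan?
#'
#' For each reference node set `N_i`, filters the scan's induced subgraph on
#' `N_i` by its own edge ranks and asks whether some step carries precisely
#' one non-trivial homology class of the reference dimension; reports the
#' first such step and its connection pattern.
#'
#' @param N_list List of integer node-index sets (each >= 3 nodes).
#' @param scan A `weighted_network`.
#' @param dimension Homology dimension of the reference class (default 1).
#' @return Tibble per node set: `set`, `n_nodes`, `cycle_found`,
#'   `first_step`, `rho` (on the subgraph's own density scale), `edges`
#'   (list column with the subgraph edges present at that step).
#' @export
rule1_nodes_form_cycle <- function(N_list, scan, dimension = 1L) {
  if (any(lengths(N_list) < 3)) abort("node sets must have at least 3 nodes")
  rows <- lapply(seq_along(N_list), function(ii) {
    N <- sort.int(unique(as.integer(N_list[[ii]])))
    sub <- induced_network(scan, N)
    filt <- build_filtration(sub)
    bc <- betti_curves(filt, max_dim = max(2L, dimension))
    hit <- which(bc[[paste0("beta_", dimension)]] == 1L)
    found <- length(hit) > 0
    first_step <- if (found) bc$step[hit[1]] else NA_integer_
    ed <- if (found) {
      filt$edges[filt$edges$step <= first_step, c("from", "to", "weight")]
    } else {
      NULL
    }
    tibble(
      set = ii,
      n_nodes = length(N),
      cycle_found = found,
      first_step = first_step,
      rho = if (found) bc$rho[hit[1]] else NA_real_,
      edges = list(ed)
    )
  })
  bind_rows(rows)
}

# cyclic order of `shared` nodes identical in both sequences, up to rotation
# and reflection
cyclic_order_preserved <- function(ref_seq, cand_seq, shared) {
  a <- ref_seq[ref_seq %in% shared]
  b <- cand_seq[cand_seq %in% shared]
  if (length(a) != length(b) || !setequal(a, b)) return(FALSE)
  n <- length(b)
  if (n <= 2) return(TRUE)
  for (r in seq_len(n)) {
    x <- c(b[r:n], if (r > 1) b[1:(r - 1)])
    if (identical(x, a) || identical(rev(x), a)) return(TRUE)
  }
  FALSE
}

# all simple cycles of length 3..max_len, each once: DFS from the smallest
# node of the cycle, second neighbour below the last to fix orientation
enum_simple_cycles <- function(edges_ij, n, max_len) {
  nbrs <- vector("list", n)
  for (r in seq_len(nrow(edges_ij))) {
    a <- edges_ij[r, 1]
    b <- edges_ij[r, 2]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  out <- list()
  path <- integer(max_len)
  visit <- function(s, v, depth) {
    for (w in nbrs[[v]]) {
      if (w == s && depth >= 3) {
        if (path[2] < v) out[[length(out) + 1L]] <<- path[seq_len(depth)]
      } else if (w > s && depth < max_len && !(w %in% path[seq_len(depth)])) {
        path[depth + 1L] <<- w
        visit(s, w, depth + 1L)
      }
    }
  }
  for (s in seq_len(n)) {
    if (length(nbrs[[s]]) < 2) next
    path[1] <- s
    visit(s, s, 1L)
  }
  out
}

# candidate cycles for subrule 2b at one slice: simple cycles of bounded
# length, in the same class as `gen_chain`, meeting the node-overlap and
# order conditions for some reference representative
rule2b_holds <- function(reference, fc, filt, gen_chain, at_step, max_len) {
  ed <- filt$edges[filt$edges$step <= at_step, ]
  if (!nrow(ed)) return(FALSE)
  cyc <- enum_simple_cycles(cbind(ed$i, ed$j), filt$n_nodes, max_len)
  for (p in cyc) {
    seqn <- as.integer(p)
    if (length(seqn) < 3) next
    cyc_nodes <- unique(seqn)
    ok_i <- FALSE
    for (ri in seq_len(nrow(reference))) {
      N <- reference$nodes[[ri]]
      if (length(intersect(cyc_nodes, N)) < length(N) - 1L) next
      if (length(setdiff(cyc_nodes, N)) > 2L) next
      shared <- intersect(cyc_nodes, N)
      if (!cyclic_order_preserved(reference$cycle_nodes[[ri]], seqn, shared)) next
      ok_i <- TRUE
      break
    }
    if (!ok_i) next
    edges <- cbind(seqn, c(seqn[-1], seqn[1]))
    edges <- t(apply(edges, 1, sort.int))
    chain <- tryCatch(
      chain_positions(edges, fc, 1L, at_step),
      error = function(e) NULL
    )
    if (is.null(chain)) next
    if (!chain_is_closed(chain, fc, 1L)) next
    if (chain_is_bounding(gf2_xor(chain, gen_chain), fc, 1L, at_step)) {
      return(TRUE)
    }
  }
  FALSE
}

# subrule 2a at one slice: a scan generator equals, or is Z2-equivalent to,
# a reference representative
rule2a_holds <- function(reference, gens, fc, at_step) {
  for (gi in seq_len(nrow(gens))) {
    gchain <- chain_positions(gens$cliques[[gi]], fc, gens$dimension[[gi]], at_step)
    for (ri in seq_len(nrow(reference))) {
      k <- reference$dimension[[ri]]
      rchain <- tryCatch(
        chain_positions(reference$cliques[[ri]], fc, k, at_step),
        error = function(e) NULL
      )
      if (is.null(rchain)) next  # reference cliques absent from this scan slice
      if (chain_is_bounding(gf2_xor(gchain, rchain), fc, k, at_step)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Rule 2: does a scan contain a similar topological cavity?
#'
#' Scans the candidate persistence classes of the reference dimension whose
#' birth simplex contains a reference-cycle node, in order of increasing
#' birth density. Subrule (a): a minimal generator of the scan class at its
#' birth density equals, or is Z2-equivalent to, a reference representative.
#' Subrule (b, dimension 1): some cycle in the class at birth is formed by
#' at least all but one node of some reference set `N_i`, with at most two
#' additional nodes, the `N_i` nodes keeping their cyclic order (up to
#' rotation and reflection). Subrule (c): (a) or (b) holds at some density
#' in `[rho_birth, rho_death)`. The first match is returned. A class whose
#' birth simplex avoids every reference node is never examined — the
#' procedure's documented false-negative mode.
#'
#' @param reference Representatives tibble from [minimal_1cycles()] or
#'   [minimal_2cycles()] computed on the reference network.
#' @param scan A `weighted_network`.
#' @param rep_cap Cap on scan representatives per candidate class.
#' @return One-row tibble: `matched`, `subrule` (`"a"`, `"b"`, `"c"` or
#'   `NA`), `step` and `rho` where the match fired, and the candidate
#'   class's `rho_birth`/`rho_death` (`NA` when unmatched).
#' @export
rule2_similar_cavity <- function(reference, scan, rep_cap = 100L) {
  k <- reference$dimension[[1]]
  stopifnot(all(reference$dimension == k))
  filt <- build_filtration(scan)
  dgm <- persistent_homology(filt, max_dim = max(2L, k))
  fc <- flag_complex(filt, max_dim = max(2L, k))
  union_N <- sort.int(unique(unlist(reference$nodes)))
  cand <- dgm[dgm$dimension == k, ]
  cand <- cand[vapply(cand$birth_simplex,
                      function(s) any(s %in% union_N), logical(1)), ]
  cand <- cand[order(cand$birth_step), ]
  max_len <- max(lengths(reference$nodes)) + 2L
  no_match <- tibble(
    matched = FALSE, subrule = NA_character_,
    step = NA_integer_, rho = NA_real_,
    rho_birth = NA_real_, rho_death = NA_real_
  )
  if (!nrow(cand)) return(no_match)
  m <- nrow(filt$edges)
  for (ci in seq_len(nrow(cand))) {
    point <- cand[ci, ]
    gens <- if (k == 1L) {
      minimal_1cycles(filt, point, cap = rep_cap)
    } else {
      minimal_2cycles(filt, point, cap = rep_cap)
    }
    b_step <- point$birth_step[[1]]
    gchain <- chain_positions(gens$cliques[[1]], fc, k, b_step)
    hit <- function(subrule, s) tibble(
      matched = TRUE, subrule = subrule,
      step = as.integer(s), rho = s / filt$n_pairs,
      rho_birth = point$rho_birth[[1]], rho_death = point$rho_death[[1]]
    )
    if (rule2a_holds(reference, gens, fc, b_step)) return(hit("a", b_step))
    if (k == 1L &&
        rule2b_holds(reference, fc, filt, gchain, b_step, max_len)) {
      return(hit("b", b_step))
    }
    d_step <- point$death_step[[1]]
    last <- if (is.na(d_step)) m else d_step - 1L
    for (s in seq_len(last - b_step) + b_step) {
      if (rule2a_holds(reference, gens, fc, s)) return(hit("c", s))
      if (k == 1L &&
          rule2b_holds(reference, fc, filt, gchain, s, max_len)) {
        return(hit("c", s))
      }
    }
  }
  no_match
}

#' Match reference cavities against an ensemble of scans
#'
#' Applies both requirements to every scan: rule 1 (the reference nodes form
#' precisely one non-trivial cycle at some density of their induced
#' subgraph) and rule 2 (a similar topological cavity exists). A scan counts
#' as carrying the cavity when both hold.
#'
#' @param reference Representatives tibble (see [rule2_similar_cavity()]).
#' @param scans List of `weighted_network` scans.
#' @param scan_ids Optional scan labels.
#' @return A `match_result` tibble, one row per scan.
#' @export
match_cavities <- function(reference, scans, scan_ids = NULL) {
  scan_ids <- scan_ids %||% paste0("scan", seq_along(scans))
  k <- reference$dimension[[1]]
  rows <- lapply(seq_along(scans), function(si) {
    r1 <- rule1_nodes_form_cycle(reference$nodes, scans[[si]], dimension = k)
    r2 <- rule2_similar_cavity(reference, scans[[si]])
    tibble(
      scan = scan_ids[si],
      dimension = k,
      rule1 = any(r1$cycle_found),
      rule1_first_rho = suppressWarnings(min(r1$rho, na.rm = TRUE)),
      rule2 = r2$matched,
      subrule = r2$subrule,
      rule2_rho = r2$rho,
      rho_birth = r2$rho_birth,
      rho_death = r2$rho_death,
      matched = any(r1$cycle_found) && r2$matched
    )
  })
  out <- bind_rows(rows)
  out$rule1_first_rho[!is.finite(out$rule1_first_rho)] <- NA_real_
  structure(out, class = c("match_result", class(tibble())))
}
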