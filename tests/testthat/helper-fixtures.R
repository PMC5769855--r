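# Fixtures and independent oracles built in code.

# network from an explicit edge list
net_from_edges <- function(n, edges, weights) {
  w <- matrix(0, n, n)
  e <- matrix(as.integer(edges), ncol = 2)
  w[e] <- weights
  w[e[, c(2, 1), drop = FALSE]] <- weights
  weighted_network(w)
}

# triangle {1,2,3} plus pendant edge (3,4)
triangle_pendant <- function(weights = c(4, 3, 2, 1)) {
  net_from_edges(4, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4)), weights)
}

complete_net <- function(n, weights = NULL, seed = 1) {
  e <- t(combn(n, 2))
  if (is.null(weights)) {
    weights <- withr::with_seed(seed, sample(seq_len(nrow(e))))
  }
  net_from_edges(n, e, weights)
}

# Erdos-Renyi with distinct uniform weights
rand_er_net <- function(n, p, seed) {
  withr::with_seed(seed, {
    e <- t(combn(n, 2))
    keep <- runif(nrow(e)) < p
    e <- e[keep, , drop = FALSE]
    if (!nrow(e)) e <- rbind(c(1L, 2L))
    net_from_edges(n, e, runif(nrow(e)))
  })
}

# geometric: inverse-distance complete network, thresholded to density rho
rand_geo_net <- function(n, seed, rho = 0.5) {
  g <- random_geometric_network(n, seed = seed)
  threshold_by_density(g$network, rho)
}

# independent oracle: maximal cliques by exhaustive subset enumeration
brute_max_cliques <- function(net) {
  a <- net$weights > 0
  n <- nrow(a)
  cliques <- list()
  for (mask in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(S)) next
    if (length(S) == 1 || all(a[S, S][upper.tri(a[S, S])])) {
      cliques[[length(cliques) + 1L]] <- S
    }
  }
  is_max <- vapply(cliques, function(S) {
    !any(vapply(cliques, function(T) {
      length(T) > length(S) && all(S %in% T)
    }, logical(1)))
  }, logical(1))
  maximal <- cliques[is_max]
  maximal[order(
    lengths(maximal),
    vapply(maximal, function(v) paste(v, collapse = ","), character(1))
  )]
}

# count alive bars of one dimension at a step, from a persistence diagram
alive_bars <- function(dgm, dim, step) {
  sum(dgm$dimension == dim &
        dgm$birth_step <= step &
        (is.na(dgm$death_step) | dgm$death_step > step))
}

# diagram/curve agreement over the full filtration (criterion machinery)
diagram_matches_oracle <- function(net, max_dim = 2) {
  filt <- build_filtration(net)
  dgm <- persistent_homology(filt, max_dim = max_dim)
  bc <- betti_curves(filt, max_dim = max_dim)
  ok <- TRUE
  for (d in seq_len(max_dim)) {
    expected <- bc[[paste0("beta_", d)]]
    got <- vapply(bc$step, function(s) alive_bars(dgm, d, s), 0)
    ok <- ok && all(got == expected)
  }
  ok
}

# scan where one reference node is bypassed by two new nodes in order
bypass_hexagon_scan <- function() {
  net_from_edges(
    7,
    rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 6), c(6, 7), c(1, 7)),
    6:1
  )
}
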