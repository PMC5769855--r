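#' Weighted communicability
#'
#' `C = exp(D^{-1/2} A D^{-1/2})` with `D = diag(s_i)` the node strengths:
#' the exact matrix exponential of the strength-normalised weight matrix.
#' The normalisation divides each `a_ij` by `sqrt(s_i s_j)`, preventing
#' high-strength nodes from dominating the walk sum; consequently `C` is
#' invariant under a global rescaling of all weights. Node communicability
#' `C_i` sums a node's communicability with all other nodes.
#'
#' @param net A `weighted_network`; every node must have positive strength.
#' @return List with `C` (n x n symmetric matrix) and `node` (tibble with
#'   per-node strength and communicability `C_i`).
#' @export
communicability <- function(net) {
  s <- node_strength(net)
  if (any(s == 0)) {
    abort(paste0(
      "isolated node(s) with zero strength: ",
      paste(net$node_ids[s == 0], collapse = ", ")
    ))
  }
  dhalf <- 1 / sqrt(s)
  M <- net$weights * outer(dhalf, dhalf)
  C <- as.matrix(Matrix::expm(Matrix::Matrix(M)))
  C <- (C + t(C)) / 2
  dimnames(C) <- list(net$node_ids, net$node_ids)
  node <- tibble(
    node = seq_along(s),
    node_id = net$node_ids,
    strength = unname(s),
    communicability = unname(rowSums(C) - diag(C))
  )
  list(C = C, node = node)
}

#' Weighted rich-club coefficient with rewired nulls
#'
#' For each degree `k`, `phi_w(k) = W_>k / sum_{l=1..E_>k} w_l^ranked`:
#' the summed weight of edges among nodes of degree greater than `k`,
#' divided by the sum of the `E_>k` largest weights anywhere in the network.
#' Significance is assessed against `n_null` degree-preserving rewired
#' networks whose original weight multiset is reassigned to the new edges by
#' rank-matching the product of the endpoints' original strengths (an
#' approximation to strength preservation), via a one-sample one-sided
#' t-test of the null sample against the observed value at alpha = 0.05.
#' Levels whose `>k` subgraph has no edges are flagged undefined.
#'
#' @param net A `weighted_network`.
#' @param n_null Number of rewired null networks (>= 2), default 1000.
#' @param seed Integer seed for the rewiring.
#' @param swaps_per_edge Attempted double-edge swaps per edge (default 10).
#' @param keep_nulls Attach the rewired null weight matrices as an
#'   attribute (for diagnostics)? Default `FALSE`.
#' @return A `rich_club` tibble: per `k`, subgraph size, `phi`, null mean /
#'   sd, `p`, and `significant`; attributes carry the rich-club node sets.
#' @export
rich_club <- function(net, n_null = 1000L, seed = 1L, swaps_per_edge = 10L,
                      keep_nulls = FALSE) {
  stopifnot(n_null >= 2)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  if (max(deg) == 0) abort("network has no edges")
  wts <- sort(network_edges(net)$weight, decreasing = TRUE)
  s0 <- node_strength(net)
  phi_of <- function(wmat, k) {
    keep <- which(deg > k)
    if (length(keep) < 2) return(c(E = 0, phi = NA_real_))
    sub <- wmat[keep, keep, drop = FALSE]
    ww <- sub[upper.tri(sub)]
    ww <- ww[ww > 0]
    if (!length(ww)) return(c(E = 0, phi = NA_real_))
    c(E = length(ww), phi = sum(ww) / sum(wts[seq_along(ww)]))
  }
  ks <- seq(0L, max(deg) - 1L)
  obs <- t(vapply(ks, function(k) phi_of(net$weights, k), c(E = 0, phi = 0)))
  nulls <- withr_seed(seed, {
    lapply(seq_len(n_null), function(r) {
      gr <- igraph::rewire(
        g, igraph::keeping_degseq(niter = swaps_per_edge * igraph::ecount(g))
      )
      el <- igraph::as_edgelist(gr, names = FALSE)
      prod_s <- s0[el[, 1]] * s0[el[, 2]]
      ord <- order(prod_s, decreasing = TRUE)
      wnew <- matrix(0, n_nodes(net), n_nodes(net))
      wassign <- numeric(nrow(el))
      wassign[ord] <- wts
      wnew[el] <- wassign
      wnew[el[, c(2, 1)]] <- wassign
      list(phi = vapply(ks, function(k) phi_of(wnew, k)[["phi"]], 0),
           w = if (keep_nulls) wnew)
    })
  })
  null_mat <- do.call(rbind, lapply(nulls, `[[`, "phi"))  # n_null x length(ks)
  out <- tibble(
    k = ks,
    n_nodes = vapply(ks, function(k) sum(deg > k), 0L),
    n_edges = as.integer(obs[, "E"]),
    phi = obs[, "phi"],
    null_mean = apply(null_mat, 2, mean),
    null_sd = apply(null_mat, 2, sd)
  )
  out$p <- vapply(seq_along(ks), function(ii) {
    x <- null_mat[, ii]
    x <- x[!is.na(x)]
    if (is.na(out$phi[ii]) || length(x) < 2 || sd(x) == 0) return(NA_real_)
    t.test(x, mu = out$phi[ii], alternative = "less")$p.value
  }, 0)
  out$significant <- !is.na(out$p) & out$p < 0.05
  members <- lapply(ks, function(k) net$node_ids[deg > k])
  structure(
    out,
    class = c("rich_club", class(tibble())),
    members = setNames(members, ks),
    n_null = n_null,
    null_weights = if (keep_nulls) lapply(nulls, `[[`, "w")
  )
}

#' k-core and s-core decomposition
#'
#' Per-node maximal core levels by iterative pruning: the k-core keeps nodes
#' while every remaining node has (binary) degree at least `k`; the s-core is
#' the analogue with summed edge weight (strength) at least `s`, scanned
#' over the sorted set of observed strengths rather than a continuous grid.
#' A node's level is the largest threshold it survives.
#'
#' The default keeps nodes with within-subgraph degree (strength) at least
#' the threshold — the standard core definition. `mode = "strict"` instead
#' requires strictly greater, for comparison with texts that phrase the
#' k-core that way.
#'
#' @param net A `weighted_network`.
#' @param mode `"standard"` (default, survive at `>= k`) or `"strict"`
#'   (survive at `> k`).
#' @return Tibble with per-node `degree`, `strength`, `k_core`, `s_core`.
#' @export
core_decomposition <- function(net, mode = c("standard", "strict")) {
  mode <- match.arg(mode)
  strict <- mode == "strict"
  a_bin <- (net$weights > 0) * 1
  k_core <- prune_core(a_bin, thresholds = seq_len(max(rowSums(a_bin))),
                       strict = strict)
  w <- net$weights
  s_levels <- sort(unique(rowSums(w)))
  s_levels <- s_levels[s_levels > 0]
  s_core <- prune_core(w, thresholds = s_levels, strict = strict)
  tibble(
    node = seq_len(n_nodes(net)),
    node_id = net$node_ids,
    degree = as.integer(rowSums(a_bin)),
    strength = unname(rowSums(w)),
    k_core = k_core,
    s_core = s_core
  )
}

# iterative pruning: for each threshold t (ascending), repeatedly delete
# nodes whose within-subgraph row sum is < t; level of a node = largest t
# survived (0 if none)
prune_core <- function(wmat, thresholds, strict = FALSE) {
  n <- nrow(wmat)
  level <- rep(0, n)
  alive <- rep(TRUE, n)
  for (t in thresholds) {
    repeat {
      rs <- rowSums(wmat[alive, alive, drop = FALSE])
      drop_local <- if (strict) rs <= t else rs < t
      if (!any(drop_local)) break
      alive[which(alive)[drop_local]] <- FALSE
      if (!any(alive)) break
    }
    if (!any(alive)) break
    level[alive] <- t
  }
  level
}
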