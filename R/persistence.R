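# Standard persistence column reduction on one boundary matrix.
# cols: GF(2) columns in filtration order; skip: cleared columns (known
# positive). Returns per-column lows (0 = reduced to zero or cleared).
reduce_boundary <- function(cols, n_rows, skip = NULL) {
  if (is.null(skip)) skip <- rep(FALSE, length(cols))
  red <- vector("list", length(cols))
  low2col <- integer(n_rows)
  lows <- integer(length(cols))
  for (jj in seq_along(cols)) {
    if (skip[jj]) next
    col <- cols[[jj]]
    while (length(col)) {
      l <- col[length(col)]
      k <- low2col[l]
      if (k == 0L) break
      col <- gf2_xor(col, red[[k]])
    }
    red[[jj]] <- col
    if (length(col)) {
      l <- col[length(col)]
      low2col[l] <- jj
      lows[jj] <- l
    }
  }
  list(lows = lows, red = red)
}

# positive edges: those whose arrival closes a cycle (endpoints already
# connected), found by union-find along the filtration order
positive_edges <- function(filt) {
  parent <- seq_len(filt$n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ed <- filt$edges
  pos <- logical(nrow(ed))
  for (s in seq_len(nrow(ed))) {
    a <- find(ed$i[s])
    b <- find(ed$j[s])
    if (a == b) pos[s] <- TRUE else parent[a] <- b
  }
  pos
}

#' Persistent homology of the weight rank clique filtration
#'
#' Computes the Z2 persistence pairs of the flag-complex filtration in
#' dimensions 1 to `max_dim`, by standard column reduction of the boundary
#' matrices with clearing (top dimension reduced first; its paired rows are
#' skipped one dimension down). Each class is reported with its birth and
#' death edge densities, its birth simplex (the edge or clique whose arrival
#' creates the class), the lifetime `rho_death - rho_birth`, and the
#' death-to-birth ratio `pi = rho_death / rho_birth`. Classes never filled
#' in — which arise whenever the input network is incomplete — have
#' `rho_death = Inf` and `pi = Inf`.
#'
#' @param filt A `wrc_filtration` (or a `weighted_network`, filtered with
#'   default tie handling).
#' @param max_dim Maximum homology dimension (default 2).
#' @param drop_zero Drop zero-persistence pairs (birth and death at the same
#'   edge step)? Default `TRUE`; set `FALSE` to retain them.
#' @return A `persistence_diagram` tibble: `dimension`, `birth_step`,
#'   `death_step`, `rho_birth`, `rho_death`, `lifetime`, `pi`,
#'   `birth_simplex` and `death_simplex` (list columns of node indices).
#' @export
persistent_homology <- function(filt, max_dim = 2, drop_zero = TRUE) {
  if (inherits(filt, "weighted_network")) filt <- build_filtration(filt)
  stopifnot(inherits(filt, "wrc_filtration"))
  fc <- flag_complex(filt, max_dim)
  top <- max_dim + 1L
  # reduce top-down with clearing
  lows <- vector("list", top)      # lows[[d]]: per d-simplex column
  skip <- vector("list", top)
  for (d in seq(top, 2L)) {
    sk <- rep(FALSE, nrow(fc$simp[[d]]))
    if (d < top) {
      paired <- lows[[d + 1L]]
      sk[paired[paired > 0L]] <- TRUE
    }
    skip[[d]] <- sk
    lows[[d]] <- reduce_boundary(fc$bnd[[d]], nrow(fc$simp[[d - 1L]]), sk)$lows
  }
  rows <- list()
  for (k in seq_len(max_dim)) {
    # positive k-simplices (class births)
    pos <- if (k == 1L) {
      positive_edges(filt)
    } else {
      lows[[k]] == 0L   # cleared or reduced to zero
    }
    lw <- lows[[k + 1L]]
    death_of <- integer(nrow(fc$simp[[k]]))      # position of killing simplex
    nz <- which(lw > 0L)
    death_of[lw[nz]] <- nz
    for (p in which(pos)) {
      b_step <- fc$step[[k]][p]
      dpos <- death_of[p]
      d_step <- if (dpos > 0L) fc$step[[k + 1L]][dpos] else NA_integer_
      rows[[length(rows) + 1L]] <- tibble(
        dimension = k,
        birth_step = b_step,
        death_step = d_step,
        birth_simplex = list(fc$simp[[k]][p, ]),
        death_simplex = list(
          if (dpos > 0L) fc$simp[[k + 1L]][dpos, ] else integer(0)
        )
      )
    }
  }
  dg <- if (length(rows)) bind_rows(rows) else {
    tibble(
      dimension = integer(0), birth_step = integer(0),
      death_step = integer(0), birth_simplex = list(), death_simplex = list()
    )
  }
  np <- filt$n_pairs
  dg <- dg |>
    mutate(
      rho_birth = .data$birth_step / np,
      rho_death = ifelse(is.na(.data$death_step), Inf, .data$death_step / np),
      lifetime = .data$rho_death - .data$rho_birth,
      pi = .data$rho_death / .data$rho_birth
    ) |>
    arrange(.data$dimension, .data$birth_step, .data$death_step) |>
    select(
      "dimension", "birth_step", "death_step", "rho_birth", "rho_death",
      "lifetime", "pi", "birth_simplex", "death_simplex"
    )
  if (drop_zero) {
    dg <- filter(dg, is.na(.data$death_step) | .data$death_step > .data$birth_step)
  }
  structure(
    dg,
    class = c("persistence_diagram", class(tibble())),
    n_pairs = np, node_ids = filt$node_ids, max_dim = max_dim
  )
}

#' Betti curves by boundary-matrix ranks
#'
#' Independent rank-based computation of the Betti numbers `beta_0 ...
#' beta_max_dim` at every filtration step (or a subset), via incremental
#' GF(2) Gaussian elimination on each boundary matrix:
#' `beta_d = n_d - rank(bd_d) - rank(bd_(d+1))`. Intended as an oracle and
#' diagnostic for the persistence diagram on small networks.
#'
#' @param filt A `wrc_filtration` (or a `weighted_network`).
#' @param max_dim Maximum dimension (default 2).
#' @param steps Integer steps to evaluate; default all `0:|E|`.
#' @return Tibble with `step`, `rho`, and `beta_0 ... beta_<max_dim>`.
#' @export
betti_curves <- function(filt, max_dim = 2, steps = NULL) {
  if (inherits(filt, "weighted_network")) filt <- build_filtration(filt)
  m <- nrow(filt$edges)
  steps <- steps %||% 0:m
  if (any(steps < 0 | steps > m)) abort("step out of range")
  fc <- flag_complex(filt, max_dim)
  top <- max_dim + 1L
  # cumulative rank of the first k columns of each boundary matrix
  cum <- vector("list", top)
  cum[[1]] <- cumrank_cols(
    lapply(seq_len(m), function(r) sort.int(c(fc$simp[[1]][r, ]))),
    fc$n_nodes
  )
  for (d in seq(2L, top)) {
    cum[[d]] <- cumrank_cols(fc$bnd[[d]], nrow(fc$simp[[d - 1L]]))
  }
  counts <- function(d, s) findInterval(s, fc$step[[d]])
  out <- tibble(step = as.integer(steps), rho = steps / filt$n_pairs)
  rank_at <- function(d, s) {
    k <- counts(d, s)
    if (k == 0L) 0L else cum[[d]][k]
  }
  out$beta_0 <- vapply(steps, function(s) fc$n_nodes - rank_at(1L, s), 0L)
  for (d in seq_len(max_dim)) {
    out[[paste0("beta_", d)]] <- vapply(
      steps,
      function(s) counts(d, s) - rank_at(d, s) - rank_at(d + 1L, s),
      0L
    )
  }
  out
}

# rank of the first k columns, for every k, by incremental elimination
cumrank_cols <- function(cols, n_rows) {
  if (!length(cols)) return(integer(0))
  pivot <- vector("list", n_rows)
  rank <- 0L
  out <- integer(length(cols))
  for (jj in seq_along(cols)) {
    col <- cols[[jj]]
    while (length(col)) {
      l <- col[length(col)]
      p <- pivot[[l]]
      if (is.null(p)) {
        pivot[[l]] <- col
        rank <- rank + 1L
        break
      }
      col <- gf2_xor(col, p)
    }
    out[jj] <- rank
  }
  out
}

#' Euler characteristic consistency check
#'
#' At each step, compares the alternating sum of simplex counts (dimensions
#' `0 ... max_dim + 1`) with the alternating sum of Betti numbers of the
#' consistently truncated complex (the top dimension contributes its full
#' boundary kernel). The two must agree at every step of any filtration.
#'
#' @inheritParams betti_curves
#' @return Tibble with `step`, `rho`, `chi_simplices`, `chi_betti`.
#' @export
euler_identity <- function(filt, max_dim = 2, steps = NULL) {
  if (inherits(filt, "weighted_network")) filt <- build_filtration(filt)
  m <- nrow(filt$edges)
  steps <- steps %||% 0:m
  fc <- flag_complex(filt, max_dim)
  top <- max_dim + 1L
  cum <- vector("list", top)
  cum[[1]] <- cumrank_cols(
    lapply(seq_len(m), function(r) sort.int(c(fc$simp[[1]][r, ]))),
    fc$n_nodes
  )
  for (d in seq(2L, top)) {
    cum[[d]] <- cumrank_cols(fc$bnd[[d]], nrow(fc$simp[[d - 1L]]))
  }
  rank_at <- function(d, s) {
    k <- findInterval(s, fc$step[[d]])
    if (k == 0L) 0L else cum[[d]][k]
  }
  chi_s <- chi_b <- integer(length(steps))
  for (ii in seq_along(steps)) {
    s <- steps[ii]
    nd <- c(fc$n_nodes, vapply(seq_len(top), function(d) findInterval(s, fc$step[[d]]), 0L))
    chi_s[ii] <- sum(nd * (-1L)^(0:top))
    betti <- integer(top + 1L)
    betti[1] <- fc$n_nodes - rank_at(1L, s)
    for (d in seq_len(top - 1L)) {
      betti[d + 1L] <- nd[d + 1L] - rank_at(d, s) - rank_at(d + 1L, s)
    }
    betti[top + 1L] <- nd[top + 1L] - rank_at(top, s)  # truncated: kernel only
    chi_b[ii] <- sum(betti * (-1L)^(0:top))
  }
  tibble(step = as.integer(steps), rho = steps / filt$n_pairs,
         chi_simplices = chi_s, chi_betti = chi_b)
}
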