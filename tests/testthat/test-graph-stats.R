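test_that("communicability matches the closed form on a single edge", {
  for (w in c(0.5, 1, 17)) {
    net <- net_from_edges(2, rbind(c(1, 2)), w)
    C <- communicability(net)$C
    expect_equal(C[1, 2], sinh(1), tolerance = 1e-9)
    expect_equal(C[1, 1], cosh(1), tolerance = 1e-9)
  }
})

test_that("communicability is invariant under global weight rescaling", {
  net <- rand_geo_net(12, seed = 41, rho = 0.6)
  scaled <- weighted_network(net$weights * 37.5, net$node_ids)
  expect_equal(communicability(net)$C, communicability(scaled)$C,
               tolerance = 1e-10)
})

test_that("communicability of disjoint components is block diagonal", {
  net <- net_from_edges(4, rbind(c(1, 2), c(3, 4)), c(2, 5))
  C <- communicability(net)$C
  expect_equal(C[1, 3], 0, tolerance = 1e-12)
  expect_equal(C[2, 4], 0, tolerance = 1e-12)
  expect_equal(C[1, 2], sinh(1), tolerance = 1e-9)
})

test_that("communicability errors on isolated nodes, naming them", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  expect_error(communicability(weighted_network(w)), "n3")
})

test_that("matrix exponential agrees with a truncated Taylor series", {
  for (seed in 1:3) {
    net <- rand_er_net(10, 0.5, seed = 300 + seed)
    s <- node_strength(net)
    if (any(s == 0)) next
    M <- net$weights / sqrt(outer(s, s))
    series <- diag(10)
    term <- diag(10)
    for (k in 1:30) {
      term <- term %*% M / k
      series <- series + term
    }
    expect_equal(communicability(net)$C, unname(series), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("rich club of a complete equal-weight graph is exactly one", {
  k6 <- weighted_network(matrix(1, 6, 6) - diag(6))
  rc <- rich_club(k6, n_null = 5, seed = 1)
  expect_true(all(rc$phi == 1))
  # complete graphs admit no rewiring: degenerate nulls flagged, not tested
  expect_true(all(is.na(rc$p)))
})

test_that("a star hub has an empty >k subgraph flagged undefined", {
  star <- net_from_edges(4, rbind(c(1, 2), c(1, 3), c(1, 4)), c(3, 2, 1))
  rc <- rich_club(star, n_null = 5, seed = 1)
  expect_true(is.na(rc$phi[rc$k == 1]))
  expect_true(all(rc$phi <= 1, na.rm = TRUE))
})

test_that("rewired nulls preserve degrees exactly and strengths approximately", {
  net <- rand_geo_net(50, seed = 77, rho = 0.15)
  rc <- rich_club(net, n_null = 20, seed = 3, keep_nulls = TRUE)
  deg0 <- rowSums(net$weights > 0)
  s0 <- rowSums(net$weights)
  cors <- vapply(attr(rc, "null_weights"), function(w) {
    expect_identical(unname(rowSums(w > 0)), unname(deg0))
    cor(unname(rowSums(w)), unname(s0), method = "spearman")
  }, 0)
  expect_true(all(cors > 0.95))
  expect_true(all(rc$phi <= 1 + 1e-12, na.rm = TRUE))
})

test_that("core levels follow iterative pruning on small fixtures", {
  k4 <- complete_net(4, weights = rep(1, 6))
  cd4 <- core_decomposition(k4)
  expect_equal(cd4$k_core, rep(3, 4))

  tp <- triangle_pendant(weights = rep(1, 4))
  cd <- core_decomposition(tp)
  expect_equal(cd$k_core, c(2, 2, 2, 1))
  # uniform weight w: s-core level is w times the k-core level
  tp2 <- triangle_pendant(weights = rep(2.5, 4))
  cd2 <- core_decomposition(tp2)
  expect_equal(cd2$s_core, 2.5 * cd2$k_core)
})

test_that("k-core levels match igraph coreness and survive relabeling", {
  for (seed in 1:4) {
    net <- rand_er_net(12, 0.4, seed = 400 + seed)
    cd <- core_decomposition(net)
    g <- igraph::graph_from_adjacency_matrix(net$weights > 0, "undirected")
    expect_equal(cd$k_core, unname(igraph::coreness(g)))

    perm <- withr::with_seed(seed, sample(12))
    relabeled <- weighted_network(net$weights[perm, perm])
    expect_equal(core_decomposition(relabeled)$k_core, cd$k_core[perm])
    expect_equal(core_decomposition(relabeled)$s_core, cd$s_core[perm])
  }
})
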