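test_that("planted fixtures yield exactly their ground-truth points", {
  ps <- planted_square()
  dgm <- persistent_homology(ps$network)
  d1 <- dgm[dgm$dimension == 1, ]
  expect_equal(nrow(d1), 1)
  expect_equal(d1$rho_birth, 4 / 6)
  expect_equal(d1$rho_death, 5 / 6)
  # the class is born by a shell edge (never the chord 1-3)
  shell <- c("1,2", "2,3", "3,4", "1,4")
  expect_true(paste(sort(d1$birth_simplex[[1]]), collapse = ",") %in% shell)

  po <- planted_octahedron()
  dgm2 <- persistent_homology(po$network)
  d2 <- dgm2[dgm2$dimension == 2, ]
  expect_equal(nrow(d2), 1)
  expect_equal(d2$rho_birth, 12 / 15)
  expect_equal(d2$rho_death, 13 / 15)
  expect_equal(sum(dgm2$dimension == 1 & !is.finite(dgm2$rho_death)), 0)
})

test_that("lifetime and pi are consistent with births and deaths", {
  pp <- planted_pentagon()
  dgm <- persistent_homology(pp$network)
  fin <- dgm[is.finite(dgm$rho_death), ]
  expect_equal(fin$lifetime, fin$rho_death - fin$rho_birth)
  expect_equal(fin$pi, fin$rho_death / fin$rho_birth)
  expect_true(all(fin$pi > 1))
  expect_true(all(fin$rho_birth > 0 & fin$rho_birth <= 1))
})

test_that("complete weighted graphs are contractible at full density", {
  for (n in c(5, 7, 10)) {
    net <- complete_net(n, seed = n)
    dgm <- persistent_homology(net)
    expect_true(all(is.finite(dgm$rho_death)),
                info = paste("complete graph n =", n))
  }
})

test_that("alive-bar counts equal rank-oracle Betti numbers at every step", {
  for (seed in 1:10) {
    net <- if (seed %% 2) {
      rand_er_net(9, 0.5, seed = 500 + seed)
    } else {
      rand_geo_net(9, seed = 500 + seed, rho = 0.6)
    }
    expect_true(diagram_matches_oracle(net), info = paste("seed", seed))
  }
})

test_that("the Euler identity holds at every filtration step", {
  for (seed in 1:5) {
    net <- rand_er_net(10, 0.55, seed = 600 + seed)
    eu <- euler_identity(build_filtration(net))
    expect_equal(eu$chi_simplices, eu$chi_betti, info = paste("seed", seed))
  }
})

test_that("the diagram is invariant under node relabeling", {
  net <- rand_er_net(10, 0.5, seed = 61)
  dgm <- persistent_homology(net)
  perm <- withr::with_seed(61, sample(10))
  relabeled <- weighted_network(net$weights[perm, perm])
  dgm2 <- persistent_homology(relabeled)
  key <- function(d) sort(paste(d$dimension, d$birth_step, d$death_step))
  expect_equal(key(dgm2), key(dgm))
})

test_that("tiny weight perturbations that keep the order keep the diagram", {
  net <- rand_er_net(10, 0.5, seed = 62)
  w <- net$weights
  up <- which(upper.tri(w) & w > 0)
  w[up] <- w[up] + withr::with_seed(1, runif(length(up), 0, 1e-9))
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  pert <- weighted_network(w)
  a <- persistent_homology(net)
  b <- persistent_homology(pert)
  expect_equal(a$dimension, b$dimension)
  expect_equal(a$birth_step, b$birth_step)
  expect_equal(a$death_step, b$death_step)
})

test_that("zero-persistence pairs are retained only on request", {
  ps <- planted_square()
  full <- persistent_homology(ps$network, drop_zero = FALSE)
  kept <- persistent_homology(ps$network)
  expect_gte(nrow(full), nrow(kept))
  zero <- full[!is.na(full$death_step) & full$death_step == full$birth_step, ]
  expect_equal(nrow(full) - nrow(kept), nrow(zero))
  expect_equal(nrow(kept[kept$dimension == 1, ]), 1)
})

test_that("betti curves handle empty and final steps", {
  net <- rand_er_net(7, 0.6, seed = 63)
  bc <- betti_curves(net)
  expect_equal(bc$beta_0[1], 7)
  expect_equal(bc$beta_1[1], 0)
  comp <- igraph::count_components(
    igraph::graph_from_adjacency_matrix(net$weights > 0, "undirected")
  )
  expect_equal(bc$beta_0[nrow(bc)], comp)
  expect_error(betti_curves(net, steps = 999), "out of range")
})
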