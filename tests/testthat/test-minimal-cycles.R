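point_of_dim <- function(dgm, d) {
  pts <- dgm[dgm$dimension == d, ]
  pts[order(-pts$lifetime), ][1, ]
}

test_that("square fixture has the unique 4-node representative", {
  ps <- planted_square()
  filt <- build_filtration(ps$network)
  dgm <- persistent_homology(filt)
  reps <- minimal_1cycles(filt, point_of_dim(dgm, 1))
  expect_equal(nrow(reps), 1)
  expect_equal(reps$nodes[[1]], 1:4)
  expect_equal(nrow(reps$cliques[[1]]), 4)
})

test_that("pentagon fixture has the unique 5-node representative", {
  pp <- planted_pentagon()
  filt <- build_filtration(pp$network)
  dgm <- persistent_homology(filt)
  reps <- minimal_1cycles(filt, point_of_dim(dgm, 1))
  expect_equal(nrow(reps), 1)
  expect_equal(reps$nodes[[1]], 1:5)
})

test_that("parallel shortest paths in distinct classes are all recorded", {
  # birth edge (1,2); two node-disjoint length-3 paths 1-3-4-2 and 1-5-6-2,
  # with no triangles, so the two 4-cycles differ by the pre-existing
  # 6-cycle class and are non-equivalent
  net <- net_from_edges(
    6,
    rbind(c(1, 3), c(3, 4), c(4, 2), c(1, 5), c(5, 6), c(6, 2), c(1, 2)),
    c(7, 6, 5, 4, 3, 2, 1)
  )
  filt <- build_filtration(net)
  dgm <- persistent_homology(filt)
  born_last <- dgm[dgm$dimension == 1 & dgm$birth_step == 7, ]
  expect_equal(nrow(born_last), 1)
  reps <- minimal_1cycles(filt, born_last)
  expect_equal(nrow(reps), 2)
  expect_equal(sort(unique(reps$class_id)), 1:2)
  expect_equal(unique(reps$n_nodes), 4)
})

test_that("representative search respects the cap as an error", {
  ps <- planted_square()
  filt <- build_filtration(ps$network)
  dgm <- persistent_homology(filt)
  expect_error(
    minimal_1cycles(filt, point_of_dim(dgm, 1), cap = 0),
    "cap"
  )
})

test_that("octahedron minimal 2-cycle is the 6-node 8-triangle shell", {
  po <- planted_octahedron()
  filt <- build_filtration(po$network)
  dgm <- persistent_homology(filt)
  pt <- point_of_dim(dgm, 2)
  reps <- minimal_2cycles(filt, pt)
  expect_equal(nrow(reps), 1)
  expect_equal(reps$n_nodes[[1]], 6)
  expect_equal(nrow(reps$cliques[[1]]), 8)
  expect_error(minimal_2cycles(filt, pt, node_cap = 5), "node_cap")
})

test_that("cycle equivalence distinguishes classes across slices", {
  ps <- planted_square()
  filt <- build_filtration(ps$network)
  square <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4))

  # with the chord present, the square bounds the two triangles
  at_death <- flag_slice(filt, 5)
  expect_true(cycles_equivalent(square, NULL, at_death, dimension = 1))
  tri_a <- rbind(c(1, 2), c(2, 3), c(1, 3))
  expect_true(cycles_equivalent(square, tri_a, at_death, dimension = 1))

  # without the chord, the square is non-trivial
  at_birth <- flag_slice(filt, 4)
  expect_false(cycles_equivalent(square, NULL, at_birth, dimension = 1))
  expect_error(cycles_equivalent(tri_a, NULL, at_birth, dimension = 1),
               "absent|not yet")

  # a triangle whose 3-clique is in the slice is trivial
  tri_net <- net_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)), 3:1)
  tri_filt <- build_filtration(tri_net)
  expect_true(cycles_equivalent(
    rbind(c(1, 2), c(1, 3), c(2, 3)), NULL, flag_slice(tri_filt, 3),
    dimension = 1
  ))
})

test_that("a tetrahedron boundary is bounding in its own flag complex", {
  k4 <- complete_net(4, weights = 6:1)
  filt <- build_filtration(k4)
  shell <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  expect_true(cycles_equivalent(
    shell, NULL, flag_slice(filt, 6), dimension = 2
  ))
})

test_that("every representative is closed and non-bounding per the oracle", {
  for (fix in list(planted_square(), planted_pentagon())) {
    filt <- build_filtration(fix$network)
    dgm <- persistent_homology(filt)
    pt <- dgm[dgm$dimension == 1, ][1, ]
    reps <- minimal_1cycles(filt, pt)
    bc <- betti_curves(filt, steps = pt$birth_step)
    expect_gte(bc$beta_1, 1)
    for (ri in seq_len(nrow(reps))) {
      edges <- reps$cliques[[ri]]
      # closed: every node appears in exactly two cycle edges
      expect_true(all(table(as.integer(edges)) == 2))
      # non-bounding at birth: not equivalent to the empty cycle
      expect_false(cycles_equivalent(
        edges, NULL, flag_slice(filt, pt$birth_step), dimension = 1
      ))
    }
  }
})
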