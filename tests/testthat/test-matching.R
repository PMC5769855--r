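pentagon_reference <- function() {
  pp <- planted_pentagon()
  filt <- build_filtration(pp$network)
  dgm <- persistent_homology(filt)
  list(
    network = pp$network,
    reps = minimal_1cycles(filt, dgm[dgm$dimension == 1, ][1, ])
  )
}

test_that("rule 1 finds the cycle in an identical scan and not in a broken one", {
  ref <- pentagon_reference()
  N <- ref$reps$nodes

  same <- rule1_nodes_form_cycle(N, ref$network)
  expect_true(same$cycle_found)
  expect_equal(same$first_step, 5)

  # shell-only scan missing one edge and with no substitute path inside N:
  # the induced subgraph stays a tree at every density
  tree_scan <- net_from_edges(
    5, rbind(c(2, 3), c(3, 4), c(4, 5), c(1, 5)), 4:1
  )
  broken <- rule1_nodes_form_cycle(N, tree_scan)
  expect_false(broken$cycle_found)

  # complete subgraph on <= 4 nodes never carries exactly one class alone
  k4 <- complete_net(4, weights = 6:1)
  r <- rule1_nodes_form_cycle(list(1:4), k4)
  expect_false(r$cycle_found)

  expect_error(rule1_nodes_form_cycle(list(1:2), ref$network), "3 nodes")
})

test_that("rule 2a fires on an identical scan at the same birth density", {
  ref <- pentagon_reference()
  res <- rule2_similar_cavity(ref$reps, ref$network)
  expect_true(res$matched)
  expect_equal(res$subrule, "a")
  expect_equal(res$rho, 5 / 10)
})

test_that("rule 2b fires when one node is bypassed in preserved order", {
  ref <- pentagon_reference()
  res <- rule2_similar_cavity(ref$reps, bypass_hexagon_scan())
  expect_true(res$matched)
  expect_equal(res$subrule, "b")
})

test_that("a scan without the shell and no substitute yields no match", {
  ref <- pentagon_reference()
  w <- matrix(0, 5, 5)
  chords <- rbind(c(1, 3), c(1, 4))
  w[chords] <- 2:1
  w[chords[, c(2, 1)]] <- 2:1
  res <- rule2_similar_cavity(ref$reps, weighted_network(w))
  expect_false(res$matched)
  expect_true(is.na(res$subrule))
})

test_that("a class whose birth edge avoids all reference nodes is skipped", {
  # documented false-negative mode: the candidate filter looks only at
  # birth edges intersecting the reference node set
  ref <- pentagon_reference()
  # disjoint square on nodes 6-9 in an enlarged scan; pentagon shell absent
  net <- net_from_edges(
    9, rbind(c(6, 7), c(7, 8), c(8, 9), c(6, 9)), c(4, 3, 2, 1)
  )
  res <- rule2_similar_cavity(ref$reps, net)
  expect_false(res$matched)
})

test_that("jitter-only ensembles match under rule 2a in every scan", {
  ref <- pentagon_reference()
  scans <- perturb_scans(ref$network, 5, weight_jitter = 0.05, seed = 11)
  m <- match_cavities(ref$reps, scans)
  expect_equal(nrow(m), 5)
  expect_true(all(m$rule1))
  expect_true(all(m$rule2))
  expect_true(all(m$subrule == "a"))
  expect_true(all(m$matched))
})

test_that("matching is deterministic in its inputs", {
  ref <- pentagon_reference()
  scans <- perturb_scans(ref$network, 2, weight_jitter = 0.2, seed = 3)
  m1 <- match_cavities(ref$reps, scans)
  m2 <- match_cavities(ref$reps, scans)
  expect_identical(m1, m2)
})

test_that("cyclic order comparison allows rotation and reflection only", {
  expect_true(cliquecavity:::cyclic_order_preserved(
    c(1, 2, 3, 4, 5), c(3, 4, 9, 5, 1, 2), c(1, 2, 3, 4, 5)
  ))
  expect_true(cliquecavity:::cyclic_order_preserved(
    c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1), c(1, 2, 3, 4, 5)
  ))
  expect_false(cliquecavity:::cyclic_order_preserved(
    c(1, 2, 3, 4, 5), c(1, 3, 2, 4, 5), c(1, 2, 3, 4, 5)
  ))
})
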