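test_that("weighted_network validates and summarises a small matrix", {
  w <- matrix(c(0, 2, 0, 2, 0, 1, 0, 1, 0), 3, 3)
  net <- weighted_network(w)
  expect_equal(n_edges(net), 2)
  expect_equal(unname(node_strength(net)), c(2, 3, 1))

  bad <- w
  bad[1, 2] <- 5
  bad[2, 1] <- 4
  expect_error(weighted_network(bad), "asymmetric")

  neg <- -w
  expect_error(weighted_network(neg), "negative")
  expect_error(weighted_network(matrix(1, 2, 2)), "diagonal")
  expect_error(weighted_network(matrix(0, 2, 3)), "square")

  zero <- weighted_network(matrix(0, 4, 4))
  expect_equal(n_edges(zero), 0)
})

test_that("read/write round trip preserves weights exactly", {
  net <- rand_er_net(8, 0.5, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(back$weights, net$weights)
  expect_identical(back$node_ids, net$node_ids)
})

test_that("metadata row count must match the node count", {
  net <- rand_er_net(5, 0.8, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path)
  writeLines(c("id,system", "n1,A", "n2,A"), meta)
  expect_error(read_network(path, metadata_path = meta), "metadata")
})

test_that("density thresholding keeps exactly the top-weight edges", {
  k4 <- complete_net(4, weights = 6:1)
  thr <- threshold_by_density(k4, 0.5)
  expect_equal(n_edges(thr), 3)
  expect_setequal(network_edges(thr)$weight, c(6, 5, 4))

  # n = 83 at rho = 0.25 retains floor(0.25 * 3403) = 850 edges
  big <- complete_net(83, seed = 5)
  expect_equal(attr(threshold_by_density(big, 0.25), "retained_edges"), 850)

  expect_equal(n_edges(threshold_by_density(k4, 1)), 6)
  expect_equal(n_edges(threshold_by_density(k4, 0)), 0)
})

test_that("thresholding errors on a tie at the cut and is monotone in rho", {
  tied <- net_from_edges(4, rbind(c(1, 2), c(1, 3), c(1, 4)), c(3, 2, 2))
  expect_error(threshold_by_density(tied, 2 / 6), "tie")
  expect_silent(threshold_by_density(tied, 2 / 6, ties = "lexicographic"))

  net <- rand_er_net(10, 0.7, seed = 3)
  prev <- character(0)
  for (rho in c(0.1, 0.3, 0.5, 0.8)) {
    ed <- network_edges(threshold_by_density(net, rho))
    cur <- paste(ed$i, ed$j)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("tiebreak noise separates ties, is bounded and reproducible", {
  tied <- net_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)), c(2, 2, 1))
  out <- add_tiebreak_noise(tied, seed = 7)
  w <- network_edges(out)$weight
  expect_equal(anyDuplicated(w), 0)
  expect_true(all(abs(w - c(2, 2, 1)) <= 1e-4))
  expect_identical(add_tiebreak_noise(tied, seed = 7)$weights, out$weights)
  expect_error(add_tiebreak_noise(tied, epsilon = 0), "positive")
})

test_that("group averaging includes zeros and checks node sets", {
  a <- net_from_edges(3, rbind(c(1, 2)), 2)
  b <- net_from_edges(3, rbind(c(1, 2)), 4)
  avg <- group_average(list(a, b))
  expect_equal(avg$weights[1, 2], 3)

  c_ <- net_from_edges(3, rbind(c(1, 3)), 6)
  avg2 <- group_average(list(a, c_))
  expect_equal(avg2$weights[1, 3], 3)
  expect_equal(avg2$weights[1, 2], 1)

  expect_identical(group_average(list(a))$weights, a$weights)

  d <- weighted_network(b$weights, node_ids = c("x", "y", "z"))
  expect_error(group_average(list(a, d)), "node set")
})

test_that("group averaging commutes with a consistent node reordering", {
  n1 <- rand_er_net(6, 0.5, seed = 21)
  n2 <- rand_er_net(6, 0.5, seed = 22)
  perm <- c(3, 1, 6, 2, 5, 4)
  reorder <- function(net) {
    weighted_network(net$weights[perm, perm], net$node_ids[perm])
  }
  direct <- reorder(group_average(list(n1, n2)))
  swapped <- group_average(list(reorder(n1), reorder(n2)))
  expect_identical(direct$weights, swapped$weights)
})
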