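test_that("walktrap separates two cliques joined by a single edge", {
  W <- block_matrix(4, 4, w = 1, bridge = 1)
  part <- walktrap_communities(W)
  oracle <- exhaustive_max_modularity(W)
  expect_true(same_partition(part$assignment, oracle$assignment))
  expect_equal(part$Q, oracle$Q, tolerance = 1e-12)
  expect_equal(sort(unique(part$assignment)), 1:2)
})

test_that("a uniform complete graph collapses to a single community", {
  W <- matrix(1, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(W) <- 0
  part <- walktrap_communities(W)
  expect_equal(length(unique(part$assignment)), 1)
  expect_equal(part$Q, 0)
})

test_that("two disconnected equal blocks give the components and Q = 0.5", {
  W <- block_matrix(4, 4, w = 1, bridge = 0)
  part <- walktrap_communities(W)
  expect_equal(length(unique(part$assignment)), 2)
  expect_equal(part$Q, 0.5)
  expect_equal(as.numeric(modularity_q(pcor_network(W), part$assignment)), 0.5)
})

test_that("modularity matches hand-computed values and validates input", {
  # two triangles joined by one edge, clique partition: Q = 5/14
  W <- matrix(0, 6, 6, dimnames = list(LETTERS[1:6], LETTERS[1:6]))
  W[1, 2] <- W[2, 3] <- W[1, 3] <- 1
  W[4, 5] <- W[5, 6] <- W[4, 6] <- 1
  W[3, 4] <- 1
  W <- W + t(W)
  asg <- stats::setNames(c(1, 1, 1, 2, 2, 2), LETTERS[1:6])
  expect_equal(as.numeric(modularity_q(pcor_network(W), asg)), 5 / 14)
  # one community: Q = 0
  expect_equal(as.numeric(modularity_q(pcor_network(W),
                                       stats::setNames(rep(1, 6), LETTERS[1:6]))),
               0)
  expect_error(modularity_q(pcor_network(W),
                            stats::setNames(rep(1, 7), LETTERS[1:7])),
               "unknown node")
  # label thresholds mirror the published usage (0.56 strong, 0.39 moderate,
  # 0.25 weak)
  expect_equal(attr(modularity_q(pcor_network(block_matrix(4, 4)),
                                 stats::setNames(rep(1:2, each = 4),
                                                 letters[1:8])), "label"),
               "strong")
  expect_equal(bridgenet:::modularity_label(0.39), "moderate")
  expect_equal(bridgenet:::modularity_label(0.25), "weak")
})

test_that("the returned Q always equals modularity recomputed on the partition", {
  for (seed in 1:6) {
    W <- abs(rand_weight_matrix(8, density = 0.45, seed = seed))
    part <- suppressWarnings(walktrap_communities(W))
    expect_equal(part$Q,
                 as.numeric(modularity_q(pcor_network(W), part$assignment)),
                 tolerance = 1e-12)
  }
})

test_that("walktrap never exceeds the exhaustive modularity maximum", {
  for (seed in 1:4) {
    W <- abs(rand_weight_matrix(7, density = 0.5, seed = seed + 20))
    part <- suppressWarnings(walktrap_communities(W))
    oracle <- exhaustive_max_modularity(W)
    expect_lte(part$Q, oracle$Q + 1e-12)
  }
})

test_that("walktrap is equivariant under node relabelling", {
  W <- abs(rand_weight_matrix(9, density = 0.4, seed = 5))
  part <- suppressWarnings(walktrap_communities(W))
  perm <- sample(9)
  Wp <- W[perm, perm]
  partp <- suppressWarnings(walktrap_communities(Wp))
  expect_true(same_partition(part$assignment, partp$assignment))
})

test_that("an edgeless network yields singletons with a warning", {
  W <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_warning(part <- walktrap_communities(W), "singleton")
  expect_equal(unname(part$assignment), 1:5)
  expect_equal(part$Q, 0)
})

test_that("isolated nodes become singletons alongside detected communities", {
  W <- block_matrix(3, 3, w = 1, bridge = 0)
  W <- rbind(cbind(W, iso = 0), iso = 0)
  rownames(W)[7] <- colnames(W)[7] <- "iso"
  part <- walktrap_communities(W)
  expect_equal(length(unique(part$assignment)), 3)
  expect_equal(sum(part$assignment == part$assignment[["iso"]]), 1)
})

test_that("partitions agree with an independent walktrap implementation", {
  fixtures <- list(block_matrix(4, 4, w = 1, bridge = 1),
                   block_matrix(5, 3, w = 0.6, bridge = 0.2),
                   {
                     W <- matrix(0, 6, 6,
                                 dimnames = list(LETTERS[1:6], LETTERS[1:6]))
                     W[1, 2] <- W[2, 3] <- W[1, 3] <- 1
                     W[4, 5] <- W[5, 6] <- W[4, 6] <- 1
                     W[3, 4] <- 1
                     W + t(W)
                   })
  for (W in fixtures) {
    ours <- walktrap_communities(W)
    gi <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                              weighted = TRUE)
    ref <- igraph::cluster_walktrap(gi, steps = 4)
    expect_true(same_partition(ours$assignment,
                               stats::setNames(igraph::membership(ref),
                                               rownames(W))))
    expect_equal(ours$Q,
                 igraph::modularity(gi, igraph::membership(ref),
                                    weights = igraph::E(gi)$weight),
                 tolerance = 1e-10)
  }
})
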