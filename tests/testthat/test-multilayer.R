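test_that("single-layer quality reduces to Newman-Girvan modularity", {
  tri2 <- two_triangles()
  layers <- array(tri2, c(6, 6, 1))
  part <- matrix(rep(1:2, each = 3), ncol = 1)
  expect_equal(multilayer_modularity(layers, part), 0.5)
  # all nodes in one module: Q = 0 by the degree-sum identity
  g <- random_stack(7, 1, seed = 5)
  expect_equal(multilayer_modularity(g, matrix(1, 7, 1)), 0,
               tolerance = 1e-12)
  # agreement with igraph's weighted modularity on a random graph
  A <- random_stack(9, 1, seed = 6)[, , 1]
  memb <- sample(rep(1:3, each = 3))
  gi <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            weighted = TRUE)
  expect_equal(multilayer_modularity(array(A, c(9, 9, 1)),
                                     matrix(memb, ncol = 1)),
               igraph::modularity(gi, memb, weights = igraph::E(gi)$weight),
               tolerance = 1e-12)
})

test_that("multilayer quality matches the direct-summation oracle", {
  set.seed(10)
  for (case in 1:8) {
    n <- sample(3:6, 1)
    L <- sample(1:4, 1)
    gamma <- sample(c(0.8, 1, 1.3), 1)
    omega <- sample(c(0, 0.5, 1), 1)
    layers <- random_stack(n, L, seed = 100 + case)
    labels <- matrix(sample.int(3, n * L, replace = TRUE), n, L)
    expect_equal(multilayer_modularity(layers, labels, gamma, omega),
                 direct_q(layers, labels, gamma, omega), tolerance = 1e-12)
  }
  # 4 nodes x 2 identical layers with the planted block partition
  A <- matrix(0.05, 4, 4)
  A[1:2, 1:2] <- 1
  A[3:4, 3:4] <- 1
  diag(A) <- 0
  layers <- array(rep(A, 2), c(4, 4, 2))
  labels <- matrix(rep(c(1, 1, 2, 2), 2), 4, 2)
  expect_equal(multilayer_modularity(layers, labels, 1, 1),
               direct_q(layers, labels, 1, 1), tolerance = 1e-12)
})

test_that("negative weights are rejected with guidance", {
  layers <- array(c(0, -1, -1, 0), c(2, 2, 1))
  expect_error(multilayer_modularity(layers, matrix(1, 2, 1)),
               "zero_negative")
  expect_error(optimize_partition(layers), "zero_negative")
})

test_that("optimization attains the exhaustive-search maximum on tiny instances", {
  # two disconnected triangles: global optimum is the triangle partition
  tri2 <- array(two_triangles(), c(6, 6, 1))
  p <- optimize_partition(tri2, multilayer_params(n_repetitions = 1, seed = 4))
  expect_equal(p$quality, 0.5)
  expect_equal(p$labels[, 1], c(1, 1, 1, 2, 2, 2))
  expect_equal(exhaustive_max_q(tri2), 0.5)
  set.seed(11)
  for (case in 1:4) {
    dims <- list(c(4, 2), c(2, 4), c(3, 2), c(2, 3))[[case]]
    layers <- random_stack(dims[1], dims[2], seed = 200 + case)
    omega <- c(0.5, 1, 0, 1)[case]
    params <- multilayer_params(omega = omega, n_repetitions = 20,
                                seed = case)
    best <- max(vapply(repeat_partitions(layers, params), `[[`, 0, "quality"))
    expect_equal(best, exhaustive_max_q(layers, omega = omega),
                 tolerance = 1e-12)
  }
})

test_that("planted multilayer blocks are recovered across layers", {
  A <- matrix(0.05, 8, 8)
  A[1:4, 1:4] <- 0.9
  A[5:8, 5:8] <- 0.9
  diag(A) <- 0
  stk <- array(rep(A, 4), c(8, 8, 4))
  p <- optimize_partition(stk, multilayer_params(n_repetitions = 1, seed = 1))
  expect_equal(p$n_modules, 2L)
  for (s in 1:4) {
    expect_equal(p$labels[, s], rep(c(1L, 2L), each = 4))
  }
  expect_equal(p$quality, multilayer_modularity(stk, p$labels))
})

test_that("optimizer quality history never decreases and runs are seeded", {
  stk <- random_stack(10, 5, seed = 30)
  p1 <- optimize_partition(stk, multilayer_params(n_repetitions = 1, seed = 8))
  p2 <- optimize_partition(stk, multilayer_params(n_repetitions = 1, seed = 8))
  expect_identical(p1$labels, p2$labels)
  expect_false(is.unsorted(attr(p1, "q_history")))
  # canonical labels: contiguous 1..K, first-seen label is 1
  expect_equal(sort(unique(as.vector(p1$labels))), seq_len(p1$n_modules))
  expect_equal(p1$labels[1, 1], 1L)
})

test_that("coupling limits behave as the theory dictates", {
  stk <- random_stack(8, 4, seed = 40)
  # omega large: one label per node across all layers
  p <- optimize_partition(stk, multilayer_params(omega = 1000,
                                                 n_repetitions = 1, seed = 2))
  expect_equal(sum(node_switch_counts(p)), 0L)
  # omega = 0: labels in a layer are invariant to the other layers' content
  p0 <- optimize_partition(stk, multilayer_params(omega = 0,
                                                  n_repetitions = 1, seed = 2))
  stk_perm <- stk[, , c(1, 4, 3, 2)]
  p0p <- optimize_partition(stk_perm, multilayer_params(omega = 0,
                                                        n_repetitions = 1,
                                                        seed = 2))
  relabel <- function(v) match(v, unique(v))
  expect_equal(relabel(p0$labels[, 1]), relabel(p0p$labels[, 1]))
  expect_equal(relabel(p0$labels[, 3]), relabel(p0p$labels[, 3]))
})

test_that("single-layer optimization is competitive with igraph Louvain", {
  A <- random_stack(12, 1, seed = 50)[, , 1]
  gi <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            weighted = TRUE)
  set.seed(1)
  ref <- igraph::cluster_louvain(gi)
  q_ref <- igraph::modularity(gi, igraph::membership(ref),
                              weights = igraph::E(gi)$weight)
  parts <- repeat_partitions(array(A, c(12, 12, 1)),
                             multilayer_params(n_repetitions = 10, seed = 3))
  q_opt <- max(vapply(parts, `[[`, 0, "quality"))
  expect_gte(q_opt, q_ref - 1e-10)
})

test_that("repeated partitions are order-stable and reproducible", {
  stk <- random_stack(6, 3, seed = 60)
  params <- multilayer_params(n_repetitions = 4, seed = 7)
  r1 <- repeat_partitions(stk, params)
  r2 <- repeat_partitions(stk, params)
  expect_equal(length(r1), 4L)
  expect_identical(lapply(r1, `[[`, "labels"), lapply(r2, `[[`, "labels"))
  # a singleton repetition equals a plain optimization call
  single <- repeat_partitions(stk, multilayer_params(n_repetitions = 1,
                                                     seed = 7))
  expect_identical(single[[1]]$labels,
                   optimize_partition(stk, multilayer_params(seed = 7))$labels)
})
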