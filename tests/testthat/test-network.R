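test_that("build_graph applies the minimum-score filter inclusively", {
  edges <- data.frame(node_a = c("A", "B", "C"),
                      node_b = c("B", "C", "D"),
                      score = c(0.5, 0.39, 0.40))
  g <- build_graph(edges, c("A", "B", "C", "D", "E"))
  expect_equal(g$weights["A", "B"], 0.5)
  expect_equal(g$weights["B", "C"], 0)      # below threshold
  expect_equal(g$weights["C", "D"], 0.40)   # exactly at threshold kept
  expect_equal(sum(g$weights["E", ]), 0)    # isolated node retained
  expect_identical(g$weights, t(g$weights))

  expect_error(build_graph(data.frame(node_a = "A", node_b = "Z",
                                      score = 0.9), c("A", "B")),
               "endpoint")
})

test_that("MCL clusters basic structures correctly", {
  # two disjoint triangles -> exactly their components
  tri <- function(a, b, c) data.frame(node_a = c(a, b, a),
                                      node_b = c(b, c, c), score = 1)
  edges <- rbind(tri("A", "B", "C"), tri("X", "Y", "Z"))
  g <- build_graph(edges, c("A", "B", "C", "X", "Y", "Z"))
  cl <- mcl_cluster(g)
  expect_true(cl$converged)
  m <- cl$membership
  expect_equal(length(unique(m)), 2L)
  expect_equal(unname(m[c("A", "B", "C")]), rep(m[["A"]], 3))
  expect_equal(unname(m[c("X", "Y", "Z")]), rep(m[["X"]], 3))

  # single edge -> one cluster; lone node -> singleton
  g2 <- build_graph(data.frame(node_a = "A", node_b = "B", score = 0.9),
                    c("A", "B", "L"))
  m2 <- mcl_cluster(g2)$membership
  expect_equal(m2[["A"]], m2[["B"]])
  expect_false(m2[["L"]] == m2[["A"]])
  expect_equal(sort(unique(unname(m2))), c(1L, 2L))
})

test_that("input components are never merged by clustering", {
  set.seed(44)
  for (rep in 1:5) {
    n <- 14
    nodes <- sprintf("n%02d", 1:n)
    block <- sample(rep(1:3, length.out = n))
    ea <- c(); eb <- c(); sc <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (block[i] == block[j] && runif(1) < 0.6) {
        ea <- c(ea, nodes[i]); eb <- c(eb, nodes[j])
        sc <- c(sc, round(runif(1, 0.4, 1), 3))
      }
    }
    g <- build_graph(data.frame(node_a = ea, node_b = eb, score = sc),
                     nodes)
    m <- mcl_cluster(g)$membership
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      g$weights > 0, mode = "undirected"))$membership
    # nodes in different input components never share an MCL cluster
    for (cl_id in unique(m)) {
      expect_equal(length(unique(comp[names(m)[m == cl_id]])), 1L)
    }
  }
})

test_that("node order permutation yields the same partition", {
  tc <- two_community_graph(seed = 19)
  g1 <- build_graph(tc$edges, tc$nodes)
  set.seed(3)
  perm <- sample(tc$nodes)
  g2 <- build_graph(tc$edges, perm)
  m1 <- mcl_cluster(g1)$membership
  m2 <- mcl_cluster(g2)$membership
  expect_equal(canonical_partition(m1), canonical_partition(m2))
})

test_that("columns stay stochastic through inflation and pruning", {
  tc <- two_community_graph(seed = 23)
  g <- build_graph(tc$edges, tc$nodes)
  M <- g$weights
  diag(M) <- 1
  M <- argenrich:::normalize_columns(M)
  for (it in 1:10) {
    M <- M %*% M
    M <- argenrich:::normalize_columns(M^1.7)
    expect_equal(unname(colSums(M)), rep(1, ncol(M)), tolerance = 1e-9)
    M[M < 1e-5] <- 0
    M <- argenrich:::normalize_columns(M)
    expect_equal(unname(colSums(M)), rep(1, ncol(M)), tolerance = 1e-9)
  }
})

test_that("mcl_cluster matches the independent reference implementation", {
  tc <- two_community_graph(seed = 11)
  g <- build_graph(tc$edges, tc$nodes, min_score = 0.4)
  mine <- mcl_cluster(g, inflation = 1.7)$membership
  ref <- reference_mcl(g$weights, inflation = 1.7)
  expect_equal(canonical_partition(mine), canonical_partition(ref))
  expect_equal(length(unique(mine)), 2L)
})
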