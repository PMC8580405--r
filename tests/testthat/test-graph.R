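test_that("proportional thresholding keeps the stated number of largest edges", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(.1, .5, .2, .6, .3, .4)
  W <- W + t(W)
  g <- proportional_threshold(W, 0.3)         # round(0.3 * 6) = 2 edges
  expect_equal(attr(g, "n_edges"), 2)
  expect_equal(sum(g) / 2, 2)
  kept <- which(unclass(g) == 1 & upper.tri(g))
  expect_setequal(W[kept], c(.5, .6))

  full <- proportional_threshold(W, 1)
  expect_equal(sum(full) / 2, 6)
})

test_that("threshold ties break deterministically by index order", {
  W <- matrix(1, 5, 5); diag(W) <- 0
  g1 <- proportional_threshold(W, 0.5)
  g2 <- proportional_threshold(W, 0.5)
  expect_identical(unclass(g1), unclass(g2))
  expect_equal(attr(g1, "n_edges"), 5)        # round(10/2)
  # first edges in (row, col) order are retained
  expect_equal(g1[1, 2], 1L)
  expect_equal(g1[4, 5], 0L)
})

test_that("threshold rejects out-of-range fractions and asymmetric input", {
  W <- rand_sym_matrix(5, 1)
  expect_error(proportional_threshold(W, 0), "\\(0, 1\\]")
  expect_error(proportional_threshold(W, 1.2), "\\(0, 1\\]")
  bad <- W; bad[1, 2] <- 99
  expect_error(proportional_threshold(bad, 0.3), "symmetric")
})

test_that("node strength sums the weighted links", {
  W <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  W["A", "B"] <- W["B", "A"] <- 0.2
  W["A", "C"] <- W["C", "A"] <- 0.3
  W["B", "C"] <- W["C", "B"] <- 0.5
  expect_equal(node_strength(W), c(A = 0.5, B = 0.7, C = 0.8))
  expect_equal(unname(node_strength(matrix(0, 4, 4))), rep(0, 4))
  for (s in 1:5) {
    W <- rand_sym_matrix(20, 40 + s)
    expect_equal(node_strength(W), apply(W, 1, sum))
  }
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(node_strength(neg), "negative")
})

test_that("clustering matches hand cases and the triangle-enumeration oracle", {
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  cl <- clustering_coef(K3)
  expect_equal(unname(cl$local), rep(1, 3))
  expect_equal(cl$global, 1)

  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(unname(clustering_coef(star)$local), rep(0, 4))

  for (s in 1:50) {
    A <- rand_graph(10, runif(1, 0.2, 0.7), 700 + s)
    expect_equal(unname(clustering_coef(A)$local), oracle_clustering(A))
  }
})

test_that("characteristic path length matches hand cases and Floyd-Warshall", {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1; path3 <- path3 + t(path3)
  expect_equal(characteristic_path_length(path3)$L, 4 / 3)

  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(characteristic_path_length(K3)$L, 1)

  for (s in 1:50) {
    A <- rand_graph(12, runif(1, 0.15, 0.6), 800 + s)
    if (sum(A) == 0) next
    expect_equal(characteristic_path_length(A)$L, oracle_cpl(A))
  }
  expect_error(characteristic_path_length(matrix(0, 4, 4)), "no edges")
})

test_that("isolated nodes contribute zero path length and are flagged", {
  A <- matrix(0, 4, 4); A[1, 2] <- 1; A <- A + t(A)
  pl <- characteristic_path_length(A)
  expect_equal(unname(pl$l_i), c(1, 1, 0, 0))
  expect_equal(unname(pl$isolated), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(pl$disconnected)
})

test_that("betweenness matches hand cases and the path-enumeration oracle", {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1; path3 <- path3 + t(path3)
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))

  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(unname(betweenness_centrality(K3)), c(0, 0, 0))

  for (s in 1:50) {
    A <- rand_graph(9, runif(1, 0.2, 0.7), 900 + s)
    expect_equal(unname(betweenness_centrality(A)), oracle_betweenness(A),
                 tolerance = 1e-10)
  }
  norm <- betweenness_centrality(path3, normalized = TRUE)
  expect_equal(unname(norm), c(0, 1, 0))  # (n-1)(n-2)/2 = 1 at n = 3
})

test_that("metrics are equivariant under node relabeling", {
  W <- rand_sym_matrix(10, 77)
  perm <- sample(10)
  Wp <- W[perm, perm]
  m1 <- graph_metrics(W)
  m2 <- graph_metrics(Wp)
  expect_equal(m2$node$strength, m1$node$strength[perm])
  expect_equal(m2$node$clustering, m1$node$clustering[perm])
  expect_equal(m2$node$betweenness, m1$node$betweenness[perm])
  expect_equal(m2$global$C, m1$global$C)
  expect_equal(m2$global$L, m1$global$L)
})

test_that("thresholded metrics depend only on the weight rank order", {
  W <- rand_sym_matrix(12, 88)
  Wt <- W^3 * 10      # strictly monotone transform
  diag(Wt) <- 0
  m1 <- graph_metrics(W); m2 <- graph_metrics(Wt)
  expect_equal(m1$global$C, m2$global$C)
  expect_equal(m1$global$L, m2$global$L)
})

test_that("adding an edge never increases any shortest-path distance", {
  for (s in 1:10) {
    A <- rand_graph(8, 0.3, 1000 + s)
    free <- which(A == 0 & upper.tri(A))
    if (!length(free) || sum(A) == 0) next
    D1 <- oracle_fw(A)
    pick <- free[1]
    B <- A; B[pick] <- 1L; B <- pmax(B, t(B))
    D2 <- oracle_fw(B)
    expect_true(all(D2 <= D1))
  }
})
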