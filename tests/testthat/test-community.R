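unit_graph <- function(edges, n = max(edges)) {
  g <- igraph::make_graph(as.character(t(edges)), directed = FALSE)
  missing <- setdiff(as.character(seq_len(n)), igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  igraph::E(g)$weight <- 1
  g
}

test_that("modularity reproduces closed-form values", {
  tri <- unit_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(modularity_q(tri, rep(1, 3)), 0)         # one community
  expect_equal(modularity_q(tri, 1:3), -1 / 3)          # all singletons

  two_tri <- unit_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                              c(4, 5), c(5, 6), c(4, 6)))
  expect_equal(modularity_q(two_tri, rep(1:2, each = 3)), 0.5)

  g0 <- igraph::make_empty_graph(2, directed = FALSE)
  expect_error(modularity_q(g0, c(1, 2)), "no edges")
  expect_error(modularity_q(tri, c(1, 2)), "cover")
})

test_that("modularity is invariant to relabelling and weight rescaling", {
  set.seed(31)
  for (k in 1:10) {
    A <- random_weighted_graph(7, p = 0.5)
    g <- graph_from_adj(A)
    memb <- sample(1:3, 7, replace = TRUE)
    q <- modularity_q(g, memb)
    expect_equal(modularity_q(g, c(9, 5, 7)[memb]), q)
    g10 <- g
    igraph::E(g10)$weight <- igraph::E(g10)$weight * 10
    expect_equal(modularity_q(g10, memb), q)
    # independent implementation agreement (igraph)
    expect_equal(q, igraph::modularity(g, memb, weights = igraph::E(g)$weight))
    expect_equal(modularity_q(g, memb, gamma = 1.7),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                                    resolution = 1.7))
  }
})

test_that("Leiden finds the exact optimum on small graphs", {
  two_tri <- unit_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                              c(4, 5), c(5, 6), c(4, 6)))
  p <- leiden_partition(two_tri, seed = 1)
  expect_equal(p$Q, 0.5)
  expect_equal(p$n_communities, 2L)
  m <- p$membership
  expect_true(all(m[1:3] == m[1]) && all(m[4:6] == m[4]) && m[1] != m[4])
  expect_equal(p$Q, oracle_best_partition(two_tri))

  single <- unit_graph(rbind(c(1, 2)))
  ps <- leiden_partition(single, seed = 1)
  expect_equal(ps$n_communities, 1L)   # any split of one edge has Q < 0
})

test_that("Leiden output dominates the trivial partitions and is seeded", {
  set.seed(55)
  for (k in 1:5) {
    A <- random_weighted_graph(8, p = 0.4)
    g <- graph_from_adj(A)
    p <- leiden_partition(g, seed = k)
    expect_gte(p$Q, modularity_q(g, rep(1, 8)) - 1e-12)
    expect_gte(p$Q, modularity_q(g, 1:8) - 1e-12)
    expect_equal(modularity_q(g, p$membership), p$Q)  # Q matches recomputation
    p2 <- leiden_partition(g, seed = k)
    expect_identical(p$membership, p2$membership)
  }
})

test_that("Leiden modularity matches exhaustive search on <= 8 nodes", {
  set.seed(99)
  hits <- 0L
  trials <- 20L
  for (k in seq_len(trials)) {
    n <- sample(5:7, 1)
    g <- graph_from_adj(random_weighted_graph(n, p = 0.55))
    q_leiden <- leiden_partition(g, seed = k)$Q
    q_best <- oracle_best_partition(g)
    expect_lte(q_leiden, q_best + 1e-12)  # never above the true optimum
    if (abs(q_leiden - q_best) < 1e-10) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.95)
})

test_that("isolated nodes come out as singleton communities", {
  g <- unit_graph(rbind(c(1, 2), c(2, 3), c(1, 3)), n = 5)
  p <- leiden_partition(g, seed = 3)
  expect_setequal(p$unjoined, c("4", "5"))
  expect_setequal(unjoined_conditions(p)$rank, c(4L, 5L))
})

test_that("weighted degree and closeness match hand values", {
  star <- unit_graph(rbind(c(1, 2), c(1, 3), c(1, 4)))
  igraph::E(star)$weight <- 2
  expect_equal(unname(node_strengths(star)), c(6, 2, 2, 2))

  # 3-node path with unit lengths (identity transform)
  path <- unit_graph(rbind(c(1, 2), c(2, 3)))
  ct <- centrality_table(path, transform = "identity")
  expect_equal(ct$closeness, c(1 / 3, 1 / 2, 1 / 3))

  k4 <- unit_graph(t(combn(4, 2)))
  ct4 <- centrality_table(k4, transform = "identity")
  expect_equal(ct4$closeness, rep(1 / 3, 4))
  expect_equal(ct4$betweenness, rep(0, 4))  # all shortest paths are edges

  # star centre carries every leaf pair; leaves none
  ct_star <- centrality_table(star)
  expect_equal(ct_star$betweenness, c(choose(3, 2), 0, 0, 0))
  expect_equal(ct_star$degree, c(6, 2, 2, 2))
})

test_that("inverse transform turns strong association into proximity", {
  # two routes 1-3: direct weight 0.5 (length 2) vs via 2 with weights 2 (length 1)
  g <- igraph::make_graph(as.character(c(1, 2, 2, 3, 1, 3)), directed = FALSE)
  igraph::E(g)$weight <- c(2, 2, 0.5)
  ct <- centrality_table(g, transform = "inverse")
  expect_equal(ct$betweenness[2], 1)   # node 2 carries the 1-3 shortest path
  expect_equal(ct$closeness[1], 1 / (0.5 + 1))
})

test_that("centralities agree with a brute-force path-enumeration oracle", {
  set.seed(77)
  for (k in 1:8) {
    n <- sample(5:8, 1)
    A <- random_weighted_graph(n, p = 0.45)
    g <- graph_from_adj(A)
    ct <- centrality_table(g, transform = "inverse")
    L <- ifelse(A > 0, 1 / A, 0)
    ora <- oracle_paths(L)
    expect_equal(ct$degree, rowSums(A))
    expect_equal(ct$closeness, ora$closeness, tolerance = 1e-9)
    expect_equal(ct$betweenness, ora$betweenness, tolerance = 1e-9)
  }
})

test_that("isolated nodes get closeness 0 and component size 1", {
  g <- unit_graph(rbind(c(1, 2)), n = 3)
  ct <- centrality_table(g)
  expect_equal(ct$closeness[3], 0)
  expect_equal(ct$component_size, c(2, 2, 1))
})

test_that("top-k centrality ranks and breaks ties by prevalence rank", {
  tab <- data.frame(node = as.character(1:5), label = letters[1:5],
                    degree = c(5, 4, 3, 2, 1), closeness = rep(1, 5),
                    betweenness = c(0, 0, 7, 7, 9))
  class(tab) <- c("centrality_table", "data.frame")
  top <- top_k_centrality(tab, 3)
  expect_equal(top$degree$node, c("1", "2", "3"))
  expect_false(top$degree$tied[1])
  expect_equal(top$closeness$node, c("1", "2", "3"))  # tie-break: lowest rank
  expect_true(top$closeness$tied[1])
  expect_equal(top$betweenness$node, c("5", "3", "4"))

  # a hub dominates all three statistics by construction
  hub <- unit_graph(rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 3)))
  igraph::E(hub)$weight <- c(3, 3, 3, 3, 1)
  ct <- centrality_table(hub)
  t3 <- top_k_centrality(ct)
  expect_true(all(vapply(t3, function(d) "1" %in% d$node, logical(1))))
  expect_equal(t3$degree$node[1], "1")
  expect_equal(t3$betweenness$node[1], "1")
})
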