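edges_to_adj <- function(n, edges) {
  m <- matrix(0L, n, n)
  for (e in edges) {
    m[e[1], e[2]] <- 1L
    m[e[2], e[1]] <- 1L
  }
  m
}

test_that("closed-form graphs give the textbook metric values", {
  k4 <- as_adjacency(1 - diag(4))
  expect_equal(nodal_degree(k4), rep(3L, 4))
  expect_equal(clustering_coefficient(k4), rep(1, 4))
  expect_equal(nodal_local_efficiency(k4), rep(1, 4))
  expect_equal(nodal_global_efficiency(k4), rep(1, 4))
  expect_equal(global_efficiency(k4), 1)

  star <- as_adjacency(edges_to_adj(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5))))
  expect_equal(nodal_degree(star), c(4L, 1L, 1L, 1L, 1L))
  expect_equal(clustering_coefficient(star), rep(0, 5))
  expect_equal(nodal_local_efficiency(star), rep(0, 5))

  path3 <- as_adjacency(edges_to_adj(3, list(c(1, 2), c(2, 3))))
  d <- shortest_paths_matrix(path3)
  expect_equal(unname(d[1, 3]), 2)
  expect_equal(nodal_global_efficiency(path3), c(0.75, 1, 0.75))

  # triangle a-b-c with pendant d attached to a
  tri <- as_adjacency(edges_to_adj(4, list(c(1, 2), c(1, 3), c(2, 3), c(1, 4))))
  expect_equal(clustering_coefficient(tri), c(1 / 3, 1, 1, 0))

  # 4-cycle 1-2-3-4-1 with chord 1-3: node 1 neighbours {2,3,4},
  # induced edges 2-3 and 3-4 => E_loc(1) = 2*(1 + 1 + 1/2)/6 = 5/6
  chorded <- as_adjacency(edges_to_adj(4, list(c(1, 2), c(2, 3), c(3, 4),
                                               c(4, 1), c(1, 3))))
  expect_equal(nodal_local_efficiency(chorded)[1], 5 / 6)

  # disconnected pieces: infinite distances contribute zero efficiency
  pair2 <- as_adjacency(edges_to_adj(4, list(c(1, 2), c(3, 4))))
  d2 <- shortest_paths_matrix(pair2)
  expect_true(all(is.infinite(d2[1:2, 3:4])))
  expect_equal(nodal_global_efficiency(pair2), rep(1 / 3, 4))
  iso <- as_adjacency(edges_to_adj(3, list(c(1, 2))))
  expect_equal(nodal_global_efficiency(iso)[3], 0)
})

test_that("all four metrics match brute-force oracles on random graphs", {
  set.seed(8)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    adj <- as_adjacency(random_graph(n, runif(1, 0.15, 0.8)))
    expect_identical(nodal_degree(adj), oracle_degree(adj))
    expect_equal(clustering_coefficient(adj), oracle_clustering(adj))
    expect_equal(nodal_global_efficiency(adj), oracle_global_eff(adj))
    expect_equal(nodal_local_efficiency(adj), oracle_local_eff(adj))
    expect_equal(unname(shortest_paths_matrix(adj)), fw_distances(adj))
  }
})

test_that("hop distances agree with igraph on larger random graphs", {
  set.seed(9)
  for (rep in 1:20) {
    adj <- as_adjacency(random_graph(52, runif(1, 0.03, 0.3)))
    g <- igraph::graph_from_adjacency_matrix(unclass(adj) * 1,
                                             mode = "undirected")
    expect_equal(unname(shortest_paths_matrix(adj)),
                 unname(igraph::distances(g)))
  }
})

test_that("degree handshake holds and metrics stay in range on every sweep level", {
  set.seed(10)
  rec <- recording(matrix(rnorm(15 * 400), 15, 400), 10)
  sw <- threshold_sweep(correlation_matrix(rec))
  for (adj in sw$adjacency) {
    prof <- metric_profile(adj)
    expect_equal(sum(prof$degree), 2 * attr(adj, "edge_count"))
    expect_true(all(prof$clustering >= 0 & prof$clustering <= 1))
    expect_true(all(prof$local_efficiency >= 0 & prof$local_efficiency <= 1))
    expect_true(all(prof$global_efficiency >= 0 & prof$global_efficiency <= 1))
  }
})

test_that("degree and global efficiency never decrease when an edge is added", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(5:10, 1)
    m <- random_graph(n, 0.4)
    off <- which(m == 0 & upper.tri(m))
    if (length(off) == 0) next
    pick <- off[sample(length(off), 1)]
    m2 <- m
    m2[pick] <- 1L
    m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]
    a1 <- as_adjacency(m); a2 <- as_adjacency(m2)
    expect_true(all(nodal_degree(a2) >= nodal_degree(a1)))
    expect_true(all(nodal_global_efficiency(a2) >=
                      nodal_global_efficiency(a1) - 1e-12))
  }
})

test_that("metric_profile bundles the individual metrics and handles empty graphs", {
  set.seed(12)
  adj <- as_adjacency(random_graph(10, 0.3))
  prof <- metric_profile(adj)
  expect_equal(prof$degree, nodal_degree(adj))
  expect_equal(prof$clustering, clustering_coefficient(adj))
  expect_equal(prof$local_efficiency, nodal_local_efficiency(adj))
  expect_equal(prof$global_efficiency, nodal_global_efficiency(adj))

  empty <- as_adjacency(matrix(0L, 5, 5))
  pe <- metric_profile(empty)
  expect_true(all(pe$degree == 0) && all(pe$clustering == 0) &&
                all(pe$local_efficiency == 0) && all(pe$global_efficiency == 0))

  full <- as_adjacency(1 - diag(6))
  pf <- metric_profile(full)
  expect_true(all(pf$degree == 5) && all(pf$clustering == 1) &&
                all(pf$local_efficiency == 1) && all(pf$global_efficiency == 1))
})
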