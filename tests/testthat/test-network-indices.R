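test_that("closed-form fixtures match the index formulas", {
  # density
  expect_equal(net_density(complete_graph(4)), 1.0)
  expect_equal(net_density(matrix(0L, 91, 91)), 0.0)
  expect_equal(net_density(path_graph(3)), 2 * 2 / (9 - 3))
  expect_error(net_density(matrix(0L, 1, 1)), "2 vertices")

  # components
  expect_equal(count_components(matrix(0L, 91, 91)), 91L)
  expect_equal(count_components(adj_from_edges(5, list(c(1, 2), c(3, 4)))), 3L)
  expect_equal(count_components(path_graph(4)), 1L)

  # clustering coefficient
  expect_equal(clustering_coefficient(complete_graph(3)), 1.0)
  expect_equal(clustering_coefficient(star_graph(3)), 0.0)
  k4_minus_e <- complete_graph(4)
  k4_minus_e[1, 2] <- k4_minus_e[2, 1] <- 0L
  expect_equal(clustering_coefficient(k4_minus_e), (2 / 3 + 2 / 3 + 1 + 1) / 4)
  # degree-<2 vertices can be excluded from the average instead
  pend <- adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 1), c(3, 4)))
  expect_equal(clustering_coefficient(pend),
               (1 + 1 + 1 / 3) / 4)
  expect_equal(clustering_coefficient(pend, include_low_degree = FALSE),
               (1 + 1 + 1 / 3) / 3)

  # degree
  expect_equal(unname(degree_centrality(star_graph(4))), c(4L, 1L, 1L, 1L, 1L))

  # closeness: sums run over reachable vertices, isolates score 0
  expect_equal(unname(closeness_centrality(path_graph(3))),
               c(1 / 3, 1 / 2, 1 / 3))
  expect_equal(closeness_centrality(path_graph(4))[[1]], 1 / 6)
  expect_equal(unname(closeness_centrality(matrix(0L, 5, 5))), rep(0, 5))
  two_pairs <- adj_from_edges(5, list(c(1, 2), c(3, 4)))
  expect_equal(unname(closeness_centrality(two_pairs)), c(1, 1, 1, 1, 0))

  # betweenness: raw Freeman sums over unordered pairs
  expect_equal(unname(betweenness_centrality(path_graph(4))), c(0, 2, 2, 0))
  expect_equal(betweenness_centrality(star_graph(3))[[1]], 3)
  expect_equal(unname(betweenness_centrality(complete_graph(5))), rep(0, 5))

  # eigenvector: Perron-Frobenius vector, max entry 1
  expect_equal(as.vector(eigenvector_centrality(complete_graph(5))), rep(1, 5))
  ev <- eigenvector_centrality(star_graph(3))
  expect_equal(as.vector(ev), c(1, rep(1 / sqrt(3), 3)), tolerance = 1e-9)
  expect_equal(attr(ev, "eigenvalue"), sqrt(3), tolerance = 1e-9)
  # exact tie between isomorphic components: both retained
  two_tri <- adj_from_edges(6, list(c(1, 2), c(2, 3), c(3, 1),
                                    c(4, 5), c(5, 6), c(6, 4)))
  expect_equal(as.vector(eigenvector_centrality(two_tri)), rep(1, 6))
  # non-dominant component zeroed exactly
  tri_pair <- adj_from_edges(5, list(c(1, 2), c(2, 3), c(3, 1), c(4, 5)))
  expect_equal(as.vector(eigenvector_centrality(tri_pair)), c(1, 1, 1, 0, 0))
  expect_equal(as.vector(eigenvector_centrality(matrix(0L, 4, 4))), rep(0, 4))
})

test_that("all indices match their brute-force oracles on random graphs", {
  set.seed(1234)
  for (rep in 1:60) {
    n <- sample(2:7, 1)
    adj <- random_graph(n, stats::runif(1, 0.15, 0.85))
    expect_equal(net_density(adj), oracle_density(adj), tolerance = 1e-8)
    expect_equal(count_components(adj), oracle_components(adj))
    expect_equal(clustering_coefficient(adj), oracle_clustering(adj),
                 tolerance = 1e-8)
    expect_equal(unname(closeness_centrality(adj)), oracle_closeness(adj),
                 tolerance = 1e-8)
    expect_equal(unname(betweenness_centrality(adj)),
                 unname(oracle_betweenness(adj)), tolerance = 1e-8)
    expect_equal(as.vector(eigenvector_centrality(adj)), oracle_eigenvector(adj),
                 tolerance = 1e-8)
  }
})

test_that("indices agree with igraph on random graphs", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    adj <- random_graph(n, stats::runif(1, 0.1, 0.5))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(degree_centrality(adj)), igraph::degree(g))
    expect_equal(count_components(adj), igraph::components(g)$no)
    expect_equal(unname(betweenness_centrality(adj)),
                 igraph::betweenness(g, directed = FALSE), tolerance = 1e-8)
    expect_equal(net_density(adj), igraph::edge_density(g), tolerance = 1e-12)
    if (igraph::is_connected(g)) {
      expect_equal(unname(closeness_centrality(adj)), igraph::closeness(g),
                   tolerance = 1e-8)
      expect_equal(as.vector(eigenvector_centrality(adj)),
                   igraph::eigen_centrality(g)$vector,
                   tolerance = 1e-6)
    }
  }
})

test_that("index monotonicity and equivariance properties hold", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    adj <- random_graph(n, 0.3)
    gaps <- which(upper.tri(adj) & adj == 0L, arr.ind = TRUE)
    if (nrow(gaps) == 0L) next
    e <- gaps[sample(nrow(gaps), 1), ]
    adj2 <- adj
    adj2[e[1], e[2]] <- adj2[e[2], e[1]] <- 1L
    expect_gt(net_density(adj2), net_density(adj))
    expect_true(all(degree_centrality(adj2) >= degree_centrality(adj)))
    expect_lte(count_components(adj2), count_components(adj))

    perm <- sample(n)
    padj <- adj[perm, perm]
    expect_equal(net_density(padj), net_density(adj))
    expect_equal(clustering_coefficient(padj), clustering_coefficient(adj))
    expect_equal(unname(betweenness_centrality(padj)),
                 unname(betweenness_centrality(adj))[perm])
    expect_equal(unname(closeness_centrality(padj)),
                 unname(closeness_centrality(adj))[perm])
  }
})

test_that("power iteration satisfies the eigen equation on the dominant component", {
  set.seed(31)
  for (rep in 1:10) {
    adj <- random_graph(sample(4:12, 1), 0.35)
    if (sum(adj) == 0L) next
    ev <- eigenvector_centrality(adj)
    lam <- attr(ev, "eigenvalue")
    v <- as.vector(ev)
    on_dom <- v > 0
    resid <- (adj %*% v)[on_dom] - lam * v[on_dom]
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("closeness orders a connected network like mean geodesic distance", {
  set.seed(8)
  repeat {
    adj <- random_graph(8, 0.45)
    if (count_components(adj) == 1L) break
  }
  cl <- unname(closeness_centrality(adj))
  d <- oracle_distances(adj)
  mean_d <- rowSums(d) / (nrow(adj) - 1)
  expect_equal(rank(cl), rank(-mean_d))
})

test_that("the index table covers every network and vertex", {
  ros <- toy_roster("solo", 4, 1)
  rec <- validate_records(rec_df(list(1L, "solo", "lying", "")), ros)
  tbl <- compute_index_table(build_ensemble(rec, ros))
  expect_equal(nrow(tbl$global), 7L)
  expect_equal(nrow(tbl$local), 7L)
  expect_true(all(is.na(tbl$global$density)))  # N < 2: density undefined
  expect_equal(tbl$global$n_components, rep(1L, 7))
  expect_equal(tbl$local$degree, rep(0L, 7))
})
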