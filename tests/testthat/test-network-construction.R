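test_that("edges land only in the network of the shared activity", {
  ros <- toy_roster()
  rec <- suppressWarnings(validate_records(
    rec_df(list(1L, "A", "grazing", "B"),
           list(1L, "B", "grazing", ""),
           list(1L, "C", "grazing", ""),
           list(1L, "D", "standing", "")), ros))
  ens <- build_ensemble(rec, ros)
  expect_length(ens$networks, 7L)
  gr <- ens$networks[["grazing_p001"]]$adjacency
  expect_equal(sum(gr), 2L)
  expect_equal(gr["A", "B"], 1L)
  expect_equal(gr["B", "A"], 1L)
  # the standing animal is isolated in its own network, like everyone else
  expect_equal(sum(ens$networks[["standing_p001"]]$adjacency), 0L)
  for (a in setdiff(activities(), c("grazing", "standing"))) {
    expect_equal(sum(ens$networks[[paste0(a, "_p001")]]$adjacency), 0L)
  }
  # every network carries the full herd vertex set in roster order
  for (net in ens$networks) expect_equal(net$vertex_ids, ros$animal_id)
})

test_that("the ensemble is complete over activities x periods", {
  sim <- simulate_herd(small_config(n_periods = 5))
  ens <- build_ensemble(sim$records, sim$roster)
  expect_length(ens$networks, 7L * 5L)
  expect_setequal(names(ens$networks),
                  as.vector(outer(activities(), 1:5,
                                  function(a, p) sprintf("%s_p%03d", a, p))))
  # vertex-cases = networks x herd size
  tbl <- compute_index_table(ens)
  expect_equal(nrow(tbl$local), 7L * 5L * 91L)
})

test_that("per-period degrees count each recorded proximity pair twice", {
  sim <- simulate_herd(small_config(seed = 23, n_periods = 4))
  ens <- build_ensemble(sim$records, sim$roster)
  for (p in 1:4) {
    rec_p <- sim$records[sim$records$period_id == p, ]
    mentions <- sum(lengths(herdnet:::split_partners(rec_p$partners)))
    degs <- sum(vapply(activities(), function(a) {
      sum(ens$networks[[sprintf("%s_p%03d", a, p)]]$adjacency)
    }, numeric(1)))
    expect_equal(degs, mentions)
  }
})

test_that("construction is equivariant under roster relabeling", {
  sim <- simulate_herd(small_config(seed = 31, n_periods = 2))
  ens <- build_ensemble(sim$records, sim$roster)
  perm <- sample(nrow(sim$roster))
  ros2 <- sim$roster[perm, ]
  ens2 <- build_ensemble(sim$records, ros2)
  for (nm in names(ens$networks)) {
    a1 <- ens$networks[[nm]]$adjacency
    a2 <- ens2$networks[[nm]]$adjacency
    expect_identical(a2, a1[ros2$animal_id, ros2$animal_id])
  }
})

test_that("proximity_network rejects malformed adjacency", {
  bad <- matrix(c(0L, 1L, 0L, 0L), 2, 2)
  expect_error(proximity_network("grazing", 1, c("A", "B"), bad), "symmetric")
  expect_error(proximity_network("grazing", 1, c("A", "B"),
                                 matrix(c(1L, 0L, 0L, 0L), 2, 2)), "diagonal")
  expect_error(proximity_network("grazing", 1, c("A", "B"),
                                 matrix(c(0L, 2L, 2L, 0L), 2, 2)), "binary")
})

test_that("network files round-trip exactly in both formats", {
  set.seed(42)
  ids <- sprintf("V%02d", 1:20)
  adj <- random_graph(20, 0.2)
  dimnames(adj) <- list(ids, ids)
  net <- proximity_network("moving", 13, ids, adj)
  for (fmt in c("edgelist", "graphml")) {
    p <- withr::local_tempfile(fileext = if (fmt == "graphml") ".graphml"
                               else ".csv")
    write_network(net, p, fmt)
    back <- read_network(p, fmt, activity = "moving", period_id = 13)
    expect_identical(back$adjacency, net$adjacency)
    expect_equal(back$vertex_ids, ids)
  }
})

test_that("isolates survive serialization of an empty herd network", {
  ids <- sprintf("B%02d", 1:91)
  net <- proximity_network("wallowing", 2, ids, matrix(0L, 91, 91))
  p <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, p, "graphml")
  g <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::vcount(g), 91)
  expect_equal(igraph::ecount(g), 0)
  back <- read_network(p, "graphml")
  expect_identical(back$adjacency, net$adjacency)
  expect_equal(back$activity, "wallowing")
  expect_equal(back$period_id, 2L)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_network(net, p2, "edgelist")
  back2 <- read_network(p2, "edgelist", activity = "wallowing", period_id = 2)
  expect_identical(back2$adjacency, net$adjacency)
})
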