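path3 <- interaction_graph(rbind(c("a", "b"), c("b", "c")))
star3 <- interaction_graph(rbind(c("c", "x"), c("c", "y"), c("c", "z")))
triangle <- interaction_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")))

test_that("graphs are simple with symmetric neighbor sets", {
  expect_warning(g <- interaction_graph(rbind(c("a", "a"), c("a", "b"),
                                              c("b", "a"))),
                 "self-loop")
  expect_equal(nrow(graph_edges(g)), 1L)
  for (i in seq_along(g$adj))
    for (j in g$adj[[i]])
      expect_true(i %in% g$adj[[j]])
})

test_that("neighborhood similarity is the Dice coefficient on neighbor sets", {
  g <- interaction_graph(rbind(c("i", "a"), c("i", "b"), c("i", "c"),
                               c("j", "b"), c("j", "c"), c("j", "d")))
  expect_equal(neighborhood_similarity(g, "i", "j"), 2 / 3)
  expect_equal(neighborhood_similarity(g, "j", "i"), 2 / 3)
  # identical nonempty neighborhoods -> 1; disjoint -> 0
  g2 <- interaction_graph(rbind(c("u", "a"), c("v", "a")))
  expect_equal(neighborhood_similarity(g2, "u", "v"), 1.0)
  expect_equal(neighborhood_similarity(g, "a", "d"), 0.0)
  g3 <- interaction_graph(matrix(character(0), ncol = 2),
                          nodes = c("p", "q"))
  expect_error(neighborhood_similarity(g3, "p", "q"),
               class = "crossdx_data_error")
})

test_that("hand-computed centralities on a path graph", {
  ct <- centrality_table(path3)
  b <- which(ct$node == "b"); a <- which(ct$node == "a")
  expect_equal(ct$betweenness[b], 1)
  expect_equal(ct$stress[b], 1)
  expect_equal(ct$closeness[b], 2.0)
  expect_equal(ct$closeness[a], 1.5)
  expect_equal(ct$radiality[b], 2.0)
  expect_equal(ct$radiality[a], 1.5)
  expect_equal(ct$mnc[b], 1)
})

test_that("hand-computed centralities on star and triangle", {
  ct <- centrality_table(star3)
  c_ <- which(ct$node == "c")
  expect_equal(ct$degree[c_], 3)
  expect_equal(ct$betweenness[c_], 3)
  expect_equal(ct$stress[c_], 3)
  expect_equal(ct$mnc[c_], 1)
  expect_equal(ct$bottleneck[c_], 3)
  expect_true(all(ct$bottleneck[-c_] == 0))

  ct2 <- centrality_table(triangle)
  expect_true(all(ct2$betweenness == 0))
  expect_true(all(ct2$mnc == 2))
  expect_true(all(ct2$degree == 2))
})

test_that("bottleneck scores on a single edge and an empty graph", {
  e <- interaction_graph(rbind(c("a", "b")))
  expect_equal(unname(bottleneck_scores(e)), c(1, 1))
  g0 <- interaction_graph(matrix(character(0), ncol = 2),
                          nodes = c("a", "b", "c"))
  expect_equal(unname(bottleneck_scores(g0)), c(0, 0, 0))
})

test_that("all seven measures match the brute-force path-enumeration oracle", {
  set.seed(17)
  for (rep in 1:30) {
    g <- random_test_graph(sample(2:8, 1), runif(1))
    expect_equal(as.data.frame(centrality_table(g)), oracle_centralities(g),
                 tolerance = 1e-10)
  }
})

test_that("degree, betweenness and harmonic closeness match igraph", {
  skip_if_not_installed("igraph")
  set.seed(18)
  for (rep in 1:10) {
    g <- random_test_graph(25, 0.12)
    ig <- igraph::graph_from_data_frame(as.data.frame(graph_edges(g)),
                                        directed = FALSE,
                                        vertices = g$nodes)
    ct <- centrality_table(g)
    expect_equal(ct$degree,
                 unname(igraph::degree(ig)[ct$node]))
    expect_equal(ct$betweenness,
                 unname(igraph::betweenness(ig)[ct$node]),
                 tolerance = 1e-9)
    expect_equal(ct$closeness,
                 unname(igraph::harmonic_centrality(ig,
                                                    normalized = FALSE)[ct$node]),
                 tolerance = 1e-9)
  }
})

test_that("scores on a disconnected graph equal per-component scores", {
  set.seed(19)
  g1 <- random_test_graph(6, 0.5)
  edges2 <- graph_edges(random_test_graph(5, 0.5))
  edges2[] <- sub("^n", "m", edges2)
  combined <- interaction_graph(rbind(graph_edges(g1), edges2),
                                nodes = c(g1$nodes,
                                          sub("^n", "m",
                                              random_test_graph(5, 0)$nodes)))
  ct_all <- centrality_table(combined)
  ct1 <- centrality_table(g1)
  for (m in c("degree", "betweenness", "closeness", "stress", "radiality",
              "mnc", "bottleneck")) {
    expect_equal(ct_all[[m]][match(ct1$node, ct_all$node)], ct1[[m]],
                 tolerance = 1e-10)
  }
})

test_that("hub selection finds the planted hub and is deterministic", {
  g <- generate_ppi_graph(60, 1, hub_degree = 25, density = 0.03, seed = 23)
  expect_equal(select_hubs(g, k = 10, method = "mean_rank")$node[1], "HUB1")
  expect_equal(select_hubs(g, k = 10, method = "topk_count")$node[1], "HUB1")

  all_nodes <- select_hubs(g, k = length(g$nodes))
  expect_equal(nrow(all_nodes), length(g$nodes))

  # symmetric positions tie-break lexicographically, reproducibly
  sel <- select_hubs(path3, k = 3)
  expect_equal(sel$node, c("b", "a", "c"))
  expect_identical(sel$node, select_hubs(path3, k = 3)$node)
  expect_error(select_hubs(path3, k = 0), class = "crossdx_config_error")
})

test_that("regulator ranking counts distinct targets per kind", {
  net <- data.frame(
    regulator = c("TF1", "TF1", "TF2", "TF3", "mir1", "mir1", "mir2"),
    kind = c("TF", "TF", "TF", "TF", "miRNA", "miRNA", "miRNA"),
    gene = c("A", "B", "A", "Z", "A", "B", "B"))
  rk <- rank_regulators(net, c("A", "B"))
  tf <- rk[rk$kind == "TF", ]
  expect_equal(tf$regulator, c("TF1", "TF2"))  # TF3 hits nothing
  expect_equal(tf$n_targets, c(2L, 1L))
  mi <- rk[rk$kind == "miRNA", ]
  expect_equal(mi$regulator, c("mir1", "mir2"))
  expect_equal(rank_regulators(net, c("A", "B"), top_n = 1)$regulator,
               c("TF1", "mir1"))
  expect_error(rank_regulators(net, character(0)),
               class = "crossdx_config_error")
})

test_that("networks survive TSV and SIF round trips", {
  g <- random_test_graph(10, 0.3)
  tsv <- tempfile(fileext = ".tsv"); sif <- tempfile(fileext = ".sif")
  write_network(g, tsv, "tsv")
  write_network(g, sif, "sif")
  expect_identical(graph_edges(read_network(tsv)), graph_edges(g))
  expect_identical(graph_edges(read_network(sif)), graph_edges(g))
})
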