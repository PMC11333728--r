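test_that("planted class counts match the configuration exactly", {
  cfg <- simulation_config(seed = 11, n_genes = 1000, n_shared_up = 50,
                           n_shared_down = 20, n_specific_per_disease = 30,
                           n_datasets_per_disease = 2,
                           samples_per_group = list(
                             list(c(6, 6), c(8, 8)),
                             list(c(6, 6), c(8, 8))))
  sim <- generate_two_disease_studies(cfg)
  counts <- table(sim$truth$class)
  expect_equal(unname(counts["shared_up"]), 50)
  expect_equal(unname(counts["shared_down"]), 20)
  expect_equal(unname(counts["specific_disease1"]), 30)
  expect_equal(unname(counts["specific_disease2"]), 30)
  expect_equal(unname(counts["null"]), 870)
  null_rows <- sim$truth[sim$truth$class == "null", ]
  expect_true(all(null_rows$effect_disease1 == 0))
  expect_true(all(null_rows$effect_disease2 == 0))
  # study design honoured, intensities strictly positive
  expect_length(sim$studies$disease1, 2)
  expect_equal(sim$studies$disease1[[1]]$n1, 6)
  expect_equal(sim$studies$disease2[[2]]$n2, 8)
  expect_true(all(vapply(unlist(sim$studies, recursive = FALSE),
                         function(s) all(s$matrix > 0), logical(1))))
})

test_that("identical config and seed give identical studies", {
  cfg <- simulation_config(seed = 5, n_genes = 200, n_shared_up = 10,
                           n_shared_down = 5, n_specific_per_disease = 5,
                           n_datasets_per_disease = 2,
                           samples_per_group = list(
                             list(c(4, 4), c(4, 4)),
                             list(c(4, 4), c(4, 4))))
  a <- generate_two_disease_studies(cfg)
  b <- generate_two_disease_studies(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$studies$disease1[[2]]$matrix,
                   b$studies$disease1[[2]]$matrix)
  expect_identical(a$studies$disease2[[1]]$matrix,
                   b$studies$disease2[[1]]$matrix)
})

test_that("planted cross-disease effect correlation is near the target", {
  cfg <- simulation_config(seed = 21, n_genes = 500, n_shared_up = 120,
                           n_shared_down = 0, n_specific_per_disease = 0,
                           effect_mean = 1.5,
                           cross_disease_effect_correlation = 0.8)
  sim <- generate_two_disease_studies(cfg)
  sh <- sim$truth[sim$truth$class == "shared_up", ]
  expect_lt(abs(cor(sh$effect_disease1, sh$effect_disease2) - 0.8), 0.15)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_genes = 100, n_shared_up = 90,
                                 n_shared_down = 20),
               class = "crossdx_config_error")
  expect_error(simulation_config(cross_disease_effect_correlation = 1.2),
               class = "crossdx_config_error")
  expect_error(simulation_config(variance_prior_df = 0),
               class = "crossdx_config_error")
  expect_error(simulation_config(variance_prior_scale = -1),
               class = "crossdx_config_error")
})

test_that("the variance prior is recovered from generated data", {
  cfg <- simulation_config(seed = 31, n_genes = 2000, n_shared_up = 0,
                           n_shared_down = 0, n_specific_per_disease = 0,
                           n_datasets_per_disease = 1,
                           samples_per_group = list(list(c(12, 12)),
                                                    list(c(12, 12))))
  sim <- generate_two_disease_studies(cfg)
  fit <- fit_moderated_t(sim$studies$disease1[[1]])
  expect_lt(abs(fit$prior$d0 - 4) / 4, 0.5)
  expect_lt(abs(fit$prior$s0_sq - 0.05) / 0.05, 0.25)
})

test_that("planted-hub graphs obey their spec", {
  g <- generate_ppi_graph(10, 1, hub_degree = 8, density = 0, seed = 3)
  deg <- compute_centrality(g, "degree")
  expect_equal(unname(deg["HUB1"]), 8)
  expect_true(all(deg[setdiff(names(deg), "HUB1")] <= 1))

  g0 <- generate_ppi_graph(10, 0, hub_degree = 0, density = 0, seed = 3)
  expect_equal(nrow(graph_edges(g0)), 0L)
  expect_length(g0$nodes, 10)

  a <- generate_ppi_graph(30, 2, hub_degree = 10, density = 0.02, seed = 9)
  b <- generate_ppi_graph(30, 2, hub_degree = 10, density = 0.02, seed = 9)
  expect_identical(graph_edges(a), graph_edges(b))

  expect_error(generate_ppi_graph(5, 1, hub_degree = 6, density = 0),
               class = "crossdx_config_error")
  expect_error(generate_ppi_graph(5, 6, hub_degree = 2, density = 0),
               class = "crossdx_config_error")
})

test_that("gene-set generation plants the designated set", {
  uni <- sprintf("G%03d", 1:200)
  planted <- uni[1:10]
  coll <- generate_gene_set_collection(8, c(15, 30), uni, planted, seed = 4)
  expect_true(all(planted %in% coll$sets$PLANTED))
  expect_length(coll$sets, 8)
  coll2 <- generate_gene_set_collection(8, c(15, 30), uni, planted, seed = 4)
  expect_identical(coll$sets, coll2$sets)

  empty <- generate_gene_set_collection(0, c(5, 10), uni)
  expect_length(empty$sets, 0)
  expect_error(generate_gene_set_collection(3, c(300, 400), uni),
               class = "crossdx_config_error")
  expect_error(generate_gene_set_collection(3, c(5, 10), uni,
                                            planted_set = "NOT_THERE"),
               class = "crossdx_config_error")
})

test_that("BAS generation separates planted strong ligands", {
  b <- generate_bas_matrix(10, 8, 2, strong_mean = -9, weak_mean = -5,
                           noise_sd = 0.1, seed = 6)
  rk <- rank_bas_matrix(b)
  expect_setequal(rk$ligands$ligand[1:2], attr(b, "strong_ligands"))

  b0 <- generate_bas_matrix(5, 6, 3, strong_mean = -9, weak_mean = -5,
                            noise_sd = 0, seed = 1)
  expect_true(all(colMeans(b0[, 1:3]) == -9))

  x <- generate_bas_matrix(seed = 8)
  y <- generate_bas_matrix(seed = 8)
  expect_identical(unclass(x), unclass(y))
  expect_error(generate_bas_matrix(0, 5, 1), class = "crossdx_config_error")
  expect_error(generate_bas_matrix(5, 5, 6), class = "crossdx_config_error")
  expect_error(generate_bas_matrix(5, 5, 2, strong_mean = -5,
                                   weak_mean = -6),
               class = "crossdx_config_error")
})

test_that("expression studies survive a TSV round trip", {
  cfg <- simulation_config(seed = 41, n_genes = 50, n_shared_up = 5,
                           n_shared_down = 0, n_specific_per_disease = 0,
                           n_datasets_per_disease = 1,
                           samples_per_group = list(list(c(4, 4)),
                                                    list(c(4, 4))))
  st <- generate_two_disease_studies(cfg)$studies$disease1[[1]]
  expr <- tempfile(fileext = ".tsv"); samp <- tempfile(fileext = ".tsv")
  write_expression_study(st, expr, samp)
  back <- read_expression_study(expr, samp, study_id = st$study_id)
  expect_equal(back$matrix, st$matrix, tolerance = 1e-10)
  expect_identical(back$group, st$group)
})
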