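test_that("random connected graphs hit the requested density", {
  g <- random_connected_graph(5, 2.0, seed = 1)
  expect_equal(igraph::ecount(g), 5)
  expect_true(igraph::is_connected(g))

  g2 <- random_connected_graph(100, 5, seed = 2)
  expect_equal(igraph::ecount(g2), 250)
  expect_true(igraph::is_connected(g2))
  expect_equal(mean(igraph::degree(g2)), 5)
  expect_true(all(igraph::E(g2)$weight >= 0.5 & igraph::E(g2)$weight <= 1.5))

  expect_error(random_connected_graph(5, 1.0, seed = 1), "connectivity floor")
  expect_error(random_connected_graph(5, 5, seed = 1), "exceed")
})

test_that("generator parameters are validated", {
  expect_error(gen_params(n_nodes = 4), "at least 5")
  expect_error(gen_params(n_nodes = 100, avg_degree = 1), "floor")
  expect_error(gen_params(module_fraction = 0), "in \\(0, 1\\]")
  expect_error(gen_params(n_nodes = 100, module_fraction = 0.004), ">= 2")
  expect_error(gen_params(contrast = -1), "nonnegative")
})

test_that("planting creates the requested pattern at the exact contrast", {
  set.seed(9)
  g <- random_connected_graph(40, 3, seed = 9)
  S <- node_module(sort(sample(igraph::V(g)$name, 5)))

  pl <- plant_module(g, S, "clique", contrast = 2)
  pe <- attr(pl$S, "planted_edges")
  expect_equal(nrow(pe), 10) # C(5,2)
  expect_equal(measure_contrast(pl$g, pe), 2, tolerance = 1e-9)

  pl4 <- plant_module(g, node_module(sample(igraph::V(g)$name, 4)), "clique",
                      contrast = 1.0)
  expect_equal(nrow(attr(pl4$S, "planted_edges")), 6)
  expect_equal(measure_contrast(pl4$g, attr(pl4$S, "planted_edges")), 1.0,
               tolerance = 1e-9)

  plp <- plant_module(g, S, "path", contrast = 1.5)
  pep <- attr(plp$S, "planted_edges")
  expect_equal(nrow(pep), 4) # |S| - 1, ordered along sorted labels
  expect_identical(pep[, 1], sort(unclass(S))[1:4])
  expect_identical(pep[, 2], sort(unclass(S))[2:5])
  expect_equal(measure_contrast(plp$g, pep), 1.5, tolerance = 1e-9)

  expect_error(plant_module(g, node_module("n01"), "path"), "at least 2")
})

test_that("measured contrast is the ratio of mean weights", {
  g <- clique_graph(c("a", "b", "c", "d"), weight = 1)
  pe <- rbind(c("a", "b"), c("c", "d"))
  expect_equal(measure_contrast(g, pe), 1.0)
  igraph::E(g)$weight[igraph::get_edge_ids(g, t(pe))] <- 2
  expect_equal(measure_contrast(g, pe), 2.0)
  igraph::E(g)$weight[igraph::get_edge_ids(g, t(pe))] <- 0.5
  expect_lt(measure_contrast(g, pe), 1) # module in the sparser regime
  expect_error(measure_contrast(g, pe[0, , drop = FALSE]), "non-empty")
  expect_error(measure_contrast(clique_graph(c("a", "b")), rbind(c("a", "b"))),
               "no non-planted")
})

test_that("rewiring prunes to target while protecting bridges and pattern", {
  # identity when already at target
  g <- path_graph(letters[1:5])
  expect_same_graph(rewire_to_density(g, 4, seed = 1), g)

  # tree plus one extra edge: a cycle edge goes, the bridge c-d never does,
  # and the result is a spanning tree
  tree <- weighted_graph(data.frame(from = c("a", "a", "c"),
                                    to = c("b", "c", "d"), weight = 1))
  gx <- igraph::add_edges(tree, c("b", "c"), attr = list(weight = 1))
  pruned <- rewire_to_density(gx, 3, seed = 1)
  expect_equal(igraph::ecount(pruned), 3)
  expect_true(igraph::is_connected(pruned))
  expect_gt(igraph::get_edge_ids(pruned, c("c", "d"), error = FALSE), 0)

  # every non-bridge edge protected -> error
  expect_error(
    rewire_to_density(gx, 3, seed = 1,
                      protected_edges = rbind(c("a", "b"), c("a", "c"),
                                              c("b", "c"))),
    "protected or a bridge")
})

test_that("generate_pair is deterministic and respects its contracts", {
  p <- gen_params(n_nodes = 100, avg_degree = 5, module_fraction = 0.05,
                  contrast = 1.7, pattern = "clique", seed = 77)
  a <- generate_pair(p)
  b <- generate_pair(p)
  expect_identical(igraph::as_data_frame(a$g1), igraph::as_data_frame(b$g1))
  expect_identical(igraph::as_data_frame(a$g2), igraph::as_data_frame(b$g2))
  expect_identical(unclass(a$S), unclass(b$S))

  expect_true(igraph::is_connected(a$g1))
  expect_true(igraph::is_connected(a$g2))
  expect_equal(igraph::ecount(a$g1), 250)
  expect_equal(igraph::ecount(a$g2), 250)
  expect_equal(unname(a$contrast_planted), c(1.7, 1.7), tolerance = 1e-9)

  # Table-style cell: 1000 nodes, 0.5% module -> |S| = 5
  p2 <- gen_params(n_nodes = 1000, avg_degree = 5, module_fraction = 0.005,
                   contrast = 1, pattern = "clique", seed = 3)
  pair2 <- generate_pair(p2)
  expect_equal(length(pair2$S), 5)

  # planted pattern fully present in the S-induced subgraph after rewiring
  sub <- igraph::induced_subgraph(a$g1, unclass(a$S))
  pe <- attr(a$S, "planted_edges")
  expect_true(all(igraph::get_edge_ids(sub, t(pe), error = FALSE) > 0))
})

test_that("pair bundles round trip through files", {
  dir <- withr::local_tempdir()
  p <- gen_params(n_nodes = 30, avg_degree = 3, module_fraction = 0.1,
                  contrast = 2, pattern = "path", seed = 5)
  pair <- generate_pair(p)
  paths <- write_pair_bundle(pair, dir, prefix = "t")
  g1 <- read_weighted_graph(file.path(dir, "t_g1.edges"))
  expect_same_graph(g1, pair$g1)
  S <- read_node_module(file.path(dir, "t_module.txt"))
  expect_setequal(unclass(S), unclass(pair$S))
  meta <- jsonlite::read_json(file.path(dir, "t_meta.json"))
  expect_equal(meta$contrast, 2)
  expect_equal(meta$pattern, "path")
})
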