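test_that("spearman matrix matches the no-tie rank formula and drops flat taxa", {
  cts <- matrix(c(3L, 9L, 1L, 7L, 5L,
                  2L, 8L, 4L, 6L, 1L), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), paste0("s", 1:5)))
  sm <- spearman_matrix(otu_table(cts))
  d <- rank(cts[1, ]) - rank(cts[2, ])
  expect_equal(sm$rho["a", "b"], 1 - 6 * sum(d^2) / (5 * 24))
  # monotone transform leaves rho at 1
  x <- c(1L, 2L, 3L, 4L, 5L)
  cts2 <- rbind(a = x, b = x^3)
  colnames(cts2) <- paste0("s", 1:5)
  sm2 <- spearman_matrix(otu_table(cts2))
  expect_equal(sm2$rho["a", "b"], 1)
  expect_equal(sm2$p["a", "b"], 0)
  # zero-variance taxon dropped with warning
  cts3 <- rbind(cts, c = rep(4L, 5))
  expect_warning(sm3 <- spearman_matrix(otu_table(cts3)),
                 "zero-variance")
  expect_equal(sm3$taxa, c("a", "b"))
  # p-values agree with cor.test's t approximation
  set.seed(12)
  cts4 <- matrix(rpois(40, 10), 4,
                 dimnames = list(letters[1:4], paste0("s", 1:10)))
  sm4 <- spearman_matrix(otu_table(cts4))
  ct <- suppressWarnings(
    cor.test(cts4[1, ], cts4[2, ], method = "spearman", exact = FALSE))
  expect_equal(sm4$p["a", "b"], ct$p.value, tolerance = 1e-10)
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3); p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  # monotone in the p-ranks: sorting by p sorts q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("edge thresholds are applied jointly and isolates retained", {
  rho <- matrix(0.9, 3, 3); diag(rho) <- NA
  p <- matrix(1e-4, 3, 3); diag(p) <- NA
  dimnames(rho) <- dimnames(p) <- list(letters[1:3], letters[1:3])
  net <- build_network(rho, p)
  expect_equal(nrow(net$edges), 3)     # triangle
  # all q at 1: no edges, nodes kept as isolates
  p1 <- matrix(1, 3, 3); diag(p1) <- NA
  dimnames(p1) <- dimnames(rho)
  net0 <- build_network(rho, p1)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(nrow(net0$nodes), 3)
  expect_true(all(net0$nodes$isolated))
  # relabeling taxa never changes the edge count
  rho2 <- rho; p2 <- p
  dimnames(rho2) <- dimnames(p2) <- list(c("z", "y", "x"),
                                         c("z", "y", "x"))
  expect_equal(nrow(build_network(rho2, p2)$edges), 3)
})

test_that("global topology matches closed forms and enumeration", {
  k5 <- igraph::make_full_graph(5)
  g <- global_topology(k5)
  expect_equal(g$density, 1)
  expect_equal(g$mean_degree, 4)
  expect_equal(g$clustering_coefficient, 1)
  expect_equal(g$average_path_length, 1)
  expect_equal(g$diameter, 1)
  # path graph P4: APL = 5/3, diameter 3
  p4 <- global_topology(path_graph(4))
  expect_equal(p4$average_path_length, 5 / 3)
  expect_equal(p4$diameter, 3)
  # two disjoint triangles: modularity equals the brute-force optimum
  tri2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(3))
  got <- global_topology(tri2)
  parts <- .all_partitions(6)
  q_best <- max(vapply(parts, function(mem)
    igraph::modularity(tri2, mem), numeric(1)))
  expect_equal(got$modularity, q_best)
  expect_equal(q_best, 0.5)
  # louvain with a fixed seed is bit-reproducible
  set.seed(77)
  gr <- igraph::sample_gnp(40, 0.15)
  expect_identical(global_topology(gr, seed = 5),
                   global_topology(gr, seed = 5))
})

test_that("node topology matches enumeration oracles and symmetry", {
  s4 <- star_graph(3)
  igraph::V(s4)$name <- paste0("v", 1:4)
  nt <- node_topology(s4)
  expect_equal(nt$betweenness, c(3, 0, 0, 0))
  expect_equal(nt$eigenvector[1], 1)
  # cycle C4: perfect symmetry
  c4 <- igraph::make_ring(4)
  igraph::V(c4)$name <- paste0("v", 1:4)
  nt4 <- node_topology(c4)
  expect_true(all(nt4$degree == 2))
  expect_equal(length(unique(round(nt4$closeness, 12))), 1)
  expect_equal(nt4$eigenvector, rep(1, 4))
  # K5: every eigenvector centrality is 1 after normalisation
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("v", 1:5)
  expect_equal(node_topology(k5)$eigenvector, rep(1, 5))
  # betweenness agrees with the path-enumeration oracle on random graphs
  set.seed(21)
  for (i in 1:6) {
    g <- igraph::sample_gnp(7, 0.4)
    igraph::V(g)$name <- paste0("v", 1:7)
    expect_equal(node_topology(g)$betweenness, betweenness_oracle(g),
                 tolerance = 1e-10)
  }
  # closeness on a disconnected graph: per-component, singleton = 0
  g2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                               igraph::make_empty_graph(1,
                                                        directed = FALSE))
  igraph::V(g2)$name <- paste0("v", 1:4)
  nt2 <- node_topology(g2)
  expect_equal(nt2$closeness, c(1, 1, 1, 0))
})

test_that("srb comparison requires both groups and reports medians", {
  sim <- simulate_structured_table(150, 60, 1500, seed = 19)
  net <- suppressWarnings(
    cooccurrence_network(sim$table, taxa = taxon_ids(sim$table),
                         annotations = sim$annotations))
  cmp <- compare_srb_topology(net)
  expect_equal(cmp$metric,
               c("degree", "betweenness", "closeness", "eigenvector"))
  expect_gt(cmp$median_srb[cmp$metric == "degree"],
            cmp$median_other[cmp$metric == "degree"])
  nt <- node_topology(net)
  nt$is_srb <- FALSE
  expect_error(compare_srb_topology(nt), "no SRB")
  # identical metric values give p = 1
  flat <- tibble::tibble(taxon_id = letters[1:6],
                         is_srb = rep(c(TRUE, FALSE), 3),
                         degree = 2L, betweenness = 0, closeness = 0.5,
                         eigenvector = 1)
  expect_true(all(compare_srb_topology(flat)$p_value == 1))
})

test_that("network export writes edge list, node table, graphml", {
  sim <- simulate_structured_table(150, 40, 1000, seed = 29)
  net <- suppressWarnings(
    cooccurrence_network(sim$table, annotations = sim$annotations))
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  edges <- readr::read_tsv(paths[["edges"]], show_col_types = FALSE)
  expect_equal(nrow(edges), nrow(net$edges))
  g2 <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
})
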