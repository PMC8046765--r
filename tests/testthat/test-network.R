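toy_rrm <- function(rr, codes = NULL) {
  n <- nrow(rr)
  if (is.null(codes)) codes <- paste0("c", seq_len(n))
  dimnames(rr) <- list(codes, codes)
  structure(list(codes = codes, rr = rr,
                 counts = array(0L, c(n, n, 6)), n_patients = 0L),
            class = "rr_matrix")
}

test_that("graph construction keeps RR>1 edges, caps infinities, retains isolated nodes", {
  rr <- matrix(c(NA, 4 / 3, 5 / 6, NA), 2, 2, byrow = TRUE)
  g <- build_graph(toy_rrm(rr, c("i", "j")))
  expect_equal(igraph::gsize(g), 1)
  el <- igraph::as_edgelist(g)
  expect_equal(unname(el[1, ]), c("i", "j"))
  expect_equal(igraph::E(g)$rr, 4 / 3)

  # all RR <= 1 -> edgeless, nodes kept
  g0 <- build_graph(toy_rrm(matrix(c(NA, 0.9, 1.0, NA), 2, 2)))
  expect_equal(igraph::gsize(g0), 0)
  expect_equal(igraph::gorder(g0), 2)

  # infinity capped at the maximum finite entry
  rr3 <- matrix(NA, 3, 3)
  rr3[1, 2] <- Inf; rr3[2, 3] <- 7.2; rr3[3, 1] <- 0.4
  g3 <- build_graph(toy_rrm(rr3))
  w <- setNames(igraph::E(g3)$rr, apply(igraph::as_edgelist(g3), 1, paste,
                                        collapse = ">"))
  expect_equal(unname(w["c1>c2"]), 7.2)
  expect_equal(igraph::gsize(g3), 2)

  # threshold is exclusive: RR exactly 1 creates no edge
  g1 <- build_graph(toy_rrm(matrix(c(NA, 1, 1, NA), 2, 2)))
  expect_equal(igraph::gsize(g1), 0)
})

test_that("edge density handles complete, empty and undefined cases", {
  full <- igraph::make_full_graph(5, directed = TRUE)
  igraph::V(full)$name <- paste0("c", 1:5)
  expect_equal(edge_density(full), 1.0)
  g0 <- build_graph(toy_rrm(matrix(c(NA, 0.5, 0.5, NA), 2, 2)))
  expect_equal(edge_density(g0), 0.0)
  g1 <- igraph::make_empty_graph(1)
  expect_error(edge_density(g1), "fewer than 2")
})

test_that("reciprocity distinguishes mutual and one-way edges", {
  g2 <- igraph::graph_from_literal(a --+ b, b --+ a)
  expect_equal(reciprocity(g2), 1.0)
  g1 <- igraph::graph_from_literal(a --+ b)
  expect_equal(reciprocity(g1), 0.0)
  expect_error(reciprocity(igraph::make_empty_graph(3)), "edgeless")
})

test_that("BFS diameter returns the longest shortest path and a realizing path", {
  chain <- igraph::graph_from_literal(a --+ b, b --+ c, c --+ d)
  d <- graph_diameter(chain)
  expect_equal(d$diameter, 3)
  expect_equal(d$path, c("a", "b", "c", "d"))
  cyc <- igraph::graph_from_literal(a --+ b, b --+ a)
  expect_equal(graph_diameter(cyc)$diameter, 1)
  expect_error(graph_diameter(igraph::make_empty_graph(2)), "edgeless")
})

test_that("density, reciprocity and diameter match brute-force oracles on random graphs", {
  set.seed(301)
  for (t in 1:30) {
    g <- random_rr_graph(sample(3:8, 1), p_edge = runif(1, 0.15, 0.6))
    expect_equal(edge_density(g), brute_density(g))
    expect_equal(reciprocity(g), brute_reciprocity(g))
    expect_equal(graph_diameter(g)$diameter, brute_diameter(g))
    d <- graph_diameter(g)
    expect_equal(length(d$path) - 1, d$diameter)
  }
})

test_that("HITS solves the star graph in closed form", {
  g <- igraph::graph_from_literal(i --+ a, i --+ b, i --+ c)
  sc <- hits_centrality(g, use_weights = FALSE)
  expect_equal(unname(sc$hub["i"]), 1)
  expect_equal(unname(sc$hub[c("a", "b", "c")]), c(0, 0, 0))
  expect_equal(unname(sc$authority[c("a", "b", "c")]), c(1, 1, 1))
  expect_error(hits_centrality(igraph::make_empty_graph(2)), "edgeless")
})

test_that("HITS matches the dominant-eigenvector oracle on random weighted graphs", {
  set.seed(302)
  for (t in 1:20) {
    g <- random_rr_graph(sample(4:8, 1), p_edge = 0.4)
    sc <- hits_centrality(g)
    or <- brute_hits(g)
    expect_equal(sc$hub, or$hub, tolerance = 1e-6)
    expect_equal(sc$authority, or$authority, tolerance = 1e-6)
    expect_equal(max(sc$hub), 1)
    expect_equal(max(sc$authority), 1)
  }
})

test_that("PageRank is uniform on edgeless graphs, sums to one, and matches a linear solve", {
  g0 <- igraph::make_empty_graph(4)
  igraph::V(g0)$name <- paste0("c", 1:4)
  expect_equal(unname(pagerank_centrality(g0)), rep(0.25, 4))
  set.seed(303)
  for (t in 1:20) {
    g <- random_rr_graph(sample(4:8, 1), p_edge = 0.35)
    pr <- pagerank_centrality(g)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_equal(pr, brute_pagerank(g), tolerance = 1e-8)
  }
  expect_error(pagerank_centrality(g0, damping = 1), "damping")
  expect_error(pagerank_centrality(g0, damping = -0.1), "damping")
})

test_that("centralities are equivariant under node relabeling", {
  set.seed(304)
  g <- random_rr_graph(7, p_edge = 0.4)
  perm <- sample(7)
  gp <- igraph::permute(g, perm)
  sc <- hits_centrality(g); scp <- hits_centrality(gp)
  expect_equal(scp$hub[names(sc$hub)], sc$hub, tolerance = 1e-9)
  expect_equal(scp$authority[names(sc$authority)], sc$authority,
               tolerance = 1e-9)
  pr <- pagerank_centrality(g); prp <- pagerank_centrality(gp)
  expect_equal(prp[names(pr)], pr, tolerance = 1e-9)
})

test_that("centralities agree with igraph's implementations as a cross-check", {
  set.seed(305)
  g <- random_rr_graph(8, p_edge = 0.4)
  pr <- pagerank_centrality(g)
  pr_ig <- igraph::page_rank(g, weights = igraph::E(g)$rr, damping = 0.85)$vector
  expect_equal(pr, pr_ig[names(pr)], tolerance = 1e-6)
  sc <- hits_centrality(g)
  ig <- igraph::hits_scores(g, weights = igraph::E(g)$rr, scale = TRUE)
  expect_equal(sc$hub, ig$hub[names(sc$hub)], tolerance = 1e-6)
  expect_equal(sc$authority, ig$authority[names(sc$authority)],
               tolerance = 1e-6)
})

test_that("graph_stats bundles the summary statistics coherently", {
  set.seed(306)
  g <- random_rr_graph(6, p_edge = 0.4)
  st <- graph_stats(g)
  expect_equal(st$n_nodes, 6)
  expect_equal(st$edge_density, edge_density(g))
  expect_equal(st$reciprocity, reciprocity(g))
  expect_lte(st$diameter, st$n_nodes - 1)
  expect_true(st$edge_density >= 0 && st$edge_density <= 1)
  expect_true(st$reciprocity >= 0 && st$reciprocity <= 1)
})

test_that("centrality table is sorted and GEXF export is well-formed XML", {
  set.seed(307)
  g <- random_rr_graph(6, p_edge = 0.4)
  ct <- centrality_table(g)
  expect_equal(ct$hub, sort(ct$hub, decreasing = TRUE))
  expect_equal(max(ct$hub), 1)
  path <- tempfile(fileext = ".gexf")
  write_gexf(g, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:node", ns)), 6)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:edge", ns)),
               igraph::gsize(g))
})
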