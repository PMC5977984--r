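test_that("median-score filter keeps strictly-above-median edges among DE genes", {
  inter <- data.frame(gene_a = c("a", "a", "b", "c"),
                      gene_b = c("b", "c", "c", "d"),
                      combined_score = c(1, 2, 3, 4))
  g <- filterByMedianScore(inter, c("a", "b", "c", "d"))  # median 2.5
  expect_equal(igraph::ecount(g), 2L)
  expect_setequal(igraph::E(g)$combined_score, c(3, 4))
  # restricting DE genes drops edges with a non-DE endpoint
  g2 <- filterByMedianScore(inter, c("b", "c"))
  expect_equal(igraph::ecount(g2), 1L)
  # all-equal scores: strict inequality keeps nothing
  interEq <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                        combined_score = c(1, 1))
  expect_warning(gEmpty <- filterByMedianScore(interEq, c("a", "b", "c")),
                 "no interactions")
  expect_equal(igraph::vcount(gEmpty), 0L)
})

test_that("relative betweenness matches hand-derived values", {
  path <- igraph::graph_from_literal(A - B - C)
  b <- betweennessCentrality(path)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))
  star <- igraph::graph_from_literal(X - L1, X - L2, X - L3)
  b <- betweennessCentrality(star)
  expect_equal(unname(b["X"]), 1)
  expect_equal(unname(b[c("L1", "L2", "L3")]), c(0, 0, 0))
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(unname(betweennessCentrality(k4)), rep(0, 4))
  expect_error(betweennessCentrality(igraph::graph_from_literal(A - B)),
               ">= 3")
})

test_that("closeness is the inverse farness, component-restricted", {
  path <- igraph::graph_from_literal(A - B - C)
  cl <- closenessCentrality(path)
  expect_equal(unname(cl[c("A", "B", "C")]), c(1 / 3, 1 / 2, 1 / 3))
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(unname(closenessCentrality(k4)), rep(1 / 3, 4))
  edge <- igraph::graph_from_literal(A - B)
  expect_equal(unname(closenessCentrality(edge)), c(1, 1))
  iso <- igraph::graph_from_literal(A - B, C)
  expect_equal(unname(closenessCentrality(iso)["C"]), 0)
})

test_that("node and edge betweenness agree with exhaustive path enumeration", {
  set.seed(55)
  for (i in seq_len(30)) {
    n <- sample(4:8, 1)
    g <- randomConnectedGraph(n)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    expect_lt(max(abs(betweennessCentrality(g) - bruteNodeBetweenness(adj))),
              1e-9)
    el <- igraph::as_edgelist(g, names = FALSE)
    got <- igraph::edge_betweenness(g, directed = FALSE)
    expect_lt(max(abs(got - bruteEdgeBetweenness(adj, el))), 1e-9)
  }
})

test_that("relabeling nodes permutes but never changes centrality values", {
  g <- bridgedCliques(3)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  h <- igraph::permute(g, perm)
  expect_equal(sort(unname(betweennessCentrality(g))),
               sort(unname(betweennessCentrality(h))), tolerance = 1e-12)
  bg <- betweennessCentrality(g); bh <- betweennessCentrality(h)
  expect_equal(bg[igraph::V(g)$name], bh[igraph::V(g)$name],
               tolerance = 1e-12)
})

test_that("hub rule: strictly above all three medians simultaneously", {
  star <- igraph::graph_from_literal(X - L1, X - L2, X - L3)
  rep_ <- topologyReport(star)
  # medians by hand: degree {3,1,1,1} -> 1; betweenness {1,0,0,0} -> 0;
  # closeness {1/3,1/5,1/5,1/5} -> 1/5; only X beats all three
  med <- attr(rep_, "medians")
  expect_equal(unname(med), c(1, 0, 1 / 5))
  expect_identical(selectHubs(rep_), "X")
  # regular graph: every feature ties its median, strict rule -> no hubs
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- paste0("r", 1:5)
  expect_length(selectHubs(topologyReport(ring)), 0L)
})

test_that("hubs are a subset of nodes strictly above median degree", {
  set.seed(66)
  for (i in 1:5) {
    g <- randomConnectedGraph(sample(5:8, 1))
    rep_ <- topologyReport(g)
    above <- rep_$gene_id[rep_$degree > median(rep_$degree)]
    expect_true(all(selectHubs(rep_) %in% above))
  }
})

test_that("MCL partitions disjoint triangles into their components", {
  g <- igraph::disjoint_union(igraph::make_full_graph(3),
                              igraph::make_full_graph(3))
  igraph::V(g)$name <- paste0("t", 1:6)
  part <- mclCluster(g, inflation = 2)
  expect_true(part@converged)
  expect_equal(moduleSizes(part), c(3L, 3L))
  m <- moduleMembership(part)
  expect_equal(length(unique(m[1:3])), 1L)
  expect_equal(length(unique(m[4:6])), 1L)
  expect_false(m[1] == m[4])
  # independent structural oracle: graph components
  comp <- igraph::components(g)$membership
  expect_equal(unname(m == m[1]), unname(comp == comp[1]))
})

test_that("MCL splits bridged twin 3-cliques into the planted 3/3 modules", {
  g <- bridgedCliques(3)
  part <- mclCluster(g, inflation = 2)
  expect_true(part@converged)
  expect_equal(moduleSizes(part), c(3L, 3L))
  m <- moduleMembership(part)
  expect_equal(unname(m[paste0("g", 1:3)]), rep(m[["g1"]], 3))
  expect_equal(unname(m[paste0("g", 4:6)]), rep(m[["g4"]], 3))
  # cross-check with an independent community method
  eb <- igraph::cluster_edge_betweenness(g)
  expect_equal(unname(m == m[1]),
               unname(igraph::membership(eb) == igraph::membership(eb)[1]))
  # determinism
  part2 <- mclCluster(g, inflation = 2)
  expect_identical(moduleMembership(part2), moduleMembership(part))
})

test_that("MCL partitions are always valid covers", {
  set.seed(99)
  for (i in 1:8) {
    g <- randomConnectedGraph(sample(4:8, 1))
    part <- mclCluster(g)
    m <- moduleMembership(part)
    expect_length(m, igraph::vcount(g))
    expect_setequal(names(m), igraph::V(g)$name)
    expect_equal(sum(moduleSizes(part)), igraph::vcount(g))
  }
})

test_that("edge betweenness ranks the bridge as the unique key interaction", {
  path <- igraph::graph_from_literal(A - B - C)
  eb <- edgeBetweennessRanking(path)
  expect_equal(eb$edge_betweenness, c(2, 2))
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(edgeBetweennessRanking(tri)$edge_betweenness, rep(1, 3))
  g <- bridgedCliques(3)
  eb <- edgeBetweennessRanking(g)
  expect_equal(eb$edge_betweenness[1], 9)
  expect_setequal(unlist(eb[1, c("gene_a", "gene_b")]), c("g1", "g4"))
  expect_length(attr(eb, "key"), 1L)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  brute <- bruteEdgeBetweenness(adj, el)
  expect_equal(max(brute), 9)
  expect_equal(sum(brute == max(brute)), 1L)
})

test_that("hypergeometric module enrichment matches hand computation", {
  part <- new("ModulePartition",
              membership = c(a = 1L, b = 1L, c = 1L),
              iterations = 1L, converged = TRUE)
  universe <- letters[1:10]
  sets <- list(hit = letters[1:5])
  res <- enrichModules(part, sets, universe)
  # N=10, K=5, m=3, k=3: C(5,3)/C(10,3) = 1/12
  expect_equal(res$p_value, 1 / 12, tolerance = 1e-12)
  # zero overlap and module == universe both give p = 1
  res0 <- enrichModules(part, list(miss = letters[6:10]), universe)
  expect_equal(res0$p_value, 1)
  partAll <- new("ModulePartition",
                 membership = setNames(rep(1L, 10), universe),
                 iterations = 1L, converged = TRUE)
  resAll <- enrichModules(partAll, sets, universe)
  expect_equal(resAll$p_value, 1)
  expect_warning(resBad <- enrichModules(part, list(bad = c("zz"),
                                                    hit = letters[1:5]),
                                         universe),
                 "disjoint")
  expect_identical(resBad$gene_set, "hit")
})

test_that("GMT files parse into named gene-set lists", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), f)
  sets <- readGMT(f)
  expect_named(sets, c("setA", "setB"))
  expect_setequal(sets$setA, c("g1", "g2", "g3"))
})
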