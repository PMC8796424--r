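test_that("edge reduction collapses duplicates, reverses and self-loops", {
  raw <- data.frame(source = c("a", "b", "a", "a", "c", ""),
                    target = c("b", "a", "b", "a", "d", "x"),
                    stringsAsFactors = FALSE)
  res <- reduce_edges(raw)
  g <- res$graph
  expect_equal(igraph::ecount(g), 2)  # a-b and c-d
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_equal(res$report$dropped_self_loops, 1L)
  expect_equal(res$report$rejected_rows, 1L)
  expect_lte(res$report$kept_edges, res$report$input_rows)
  # idempotence: reducing the reduced edge list changes nothing
  el <- igraph::as_edgelist(g)
  res2 <- reduce_edges(data.frame(source = el[, 1], target = el[, 2]))
  expect_equal(igraph::ecount(res2$graph), igraph::ecount(g))
  # self-loop keep flag
  res3 <- reduce_edges(raw[1:4, ], keep_self_loops = TRUE)
  expect_equal(igraph::ecount(res3$graph), 2)

  # random multigraph vs set-based dedup oracle
  set.seed(8)
  v <- paste0("n", 1:12)
  raw2 <- data.frame(source = sample(v, 120, TRUE),
                     target = sample(v, 120, TRUE))
  res4 <- reduce_edges(raw2)
  keep <- raw2$source != raw2$target
  canon <- unique(paste(pmin(raw2$source, raw2$target)[keep],
                        pmax(raw2$source, raw2$target)[keep]))
  expect_equal(igraph::ecount(res4$graph), length(canon))
})

test_that("DEG overlap induces the right subgraph and is idempotent", {
  g <- reduce_edges(data.frame(source = c("a", "b"),
                               target = c("b", "c")))$graph
  deg <- data.frame(id = c("a.1", "a.2", "b.1"), effect = c(1, 3, -2),
                    p_value = 0.01, q_value = 0.01, mean_count = c(4, 6, 8),
                    stringsAsFactors = FALSE)
  sub <- overlap_deg(g, deg)
  expect_setequal(igraph::V(sub)$name, c("a", "b"))
  expect_equal(igraph::ecount(sub), 1)
  # isoform averaging carried onto the node
  expect_equal(igraph::V(sub)$effect[igraph::V(sub)$name == "a"], 2)
  expect_equal(igraph::V(sub)$mean_count[igraph::V(sub)$name == "a"], 5)
  # disjoint DEG set: empty graph plus flag
  none <- overlap_deg(g, data.frame(id = "zz", effect = 1, p_value = 0.1,
                                    q_value = 0.1, mean_count = 1))
  expect_equal(igraph::vcount(none), 0)
  expect_true(attr(none, "empty_overlap"))
  # DEG superset: identity subgraph
  all_deg <- data.frame(id = c("a", "b", "c"), effect = 1, p_value = 0.1,
                        q_value = 0.1, mean_count = 1)
  expect_equal(igraph::ecount(overlap_deg(g, all_deg)), igraph::ecount(g))
  # idempotence on node/edge sets
  sub2 <- overlap_deg(sub, deg)
  expect_setequal(igraph::V(sub2)$name, igraph::V(sub)$name)
  expect_equal(igraph::ecount(sub2), igraph::ecount(sub))
})

test_that("isoform effect summaries average and flag sign conflicts", {
  rows <- data.frame(effect = c(1, 3), mean_count = c(2, 4))
  s <- gene_effect_summary(rows)
  expect_equal(s$effect, 2)
  expect_equal(s$mean_count, 3)
  expect_false(s$sign_conflict)
  one <- gene_effect_summary(data.frame(effect = -1.5, mean_count = 7))
  expect_equal(one$effect, -1.5)
  conflict <- gene_effect_summary(data.frame(effect = c(2, -2),
                                             mean_count = c(1, 1)))
  expect_equal(conflict$effect, 0)
  expect_true(conflict$sign_conflict)
})

test_that("visual attributes encode sign, size and opacity contracts", {
  g <- igraph::make_graph(~ a - b)
  igraph::V(g)$effect <- c(-1, 2)
  igraph::V(g)$mean_count <- c(10, 50)
  g2 <- encode_visual_attributes(g)
  expect_setequal(igraph::V(g2)$shape, c("down", "up"))
  expect_true(all(igraph::V(g2)$opacity >= 0 & igraph::V(g2)$opacity <= 1))
  expect_equal(sort(igraph::V(g2)$size), c(2, 10))
  # single node: degenerate scaling goes to the top of the range
  g1 <- igraph::make_graph(~ solo)
  igraph::V(g1)$effect <- 1; igraph::V(g1)$mean_count <- 5
  g1 <- encode_visual_attributes(g1)
  expect_equal(igraph::V(g1)$opacity, 1)
  expect_equal(igraph::V(g1)$size, 10)
})

test_that("metrics match hand-computed values on canonical graphs", {
  path <- reduce_edges(data.frame(source = c("a", "b"),
                                  target = c("b", "c")))$graph
  m <- compute_metrics(path)
  expect_equal(m$nodes$degree[match(c("a", "b", "c"), m$nodes$gene)],
               c(1, 2, 1))
  expect_equal(m$diameter_per_component, 2)
  expect_equal(m$mean_clustering, 0)
  expect_equal(sum(m$nodes$degree), 2 * igraph::ecount(path))
  tri <- reduce_edges(data.frame(source = c("a", "b", "c"),
                                 target = c("b", "c", "a")))$graph
  mt <- compute_metrics(tri)
  expect_equal(mt$mean_clustering, 1)
  expect_equal(mt$diameter_per_component, 1)
  expect_error(compute_metrics(igraph::make_empty_graph(0)),
               class = "rnanet_validation_error")
})

test_that("betweenness and closeness equal brute-force all-pairs values", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- igraph::sample_gnp(30, 0.12)
    igraph::V(g)$name <- paste0("n", 1:30)
    m <- compute_metrics(g)
    ref <- brute_metrics(g)
    expect_equal(m$nodes$betweenness, ref$betweenness, tolerance = 1e-10)
    expect_equal(unname(m$nodes$degree), unname(ref$degree))
    expect_equal(m$nodes$closeness, ref$closeness, tolerance = 1e-10)
    expect_equal(sum(m$nodes$degree), 2 * igraph::ecount(g))
  }
})

test_that("hub extraction picks central nodes per module and merges", {
  # star: center is the hub
  star <- reduce_edges(data.frame(source = "hub",
                                  target = paste0("leaf", 1:5)))$graph
  part <- setNames(rep(1L, 6), c("hub", paste0("leaf", 1:5)))
  h <- hub_genes(star, part, centrality = "degree", top_k = 1)
  expect_equal(h$per_module[["1"]], "hub")
  # two modules, each a star; disconnected union equals per-module result
  star2 <- reduce_edges(data.frame(
    source = c(rep("hubA", 3), rep("hubB", 3)),
    target = c(paste0("a", 1:3), paste0("b", 1:3))))$graph
  part2 <- setNames(c(1L, rep(1L, 3), 2L, rep(2L, 3)),
                    c("hubA", paste0("a", 1:3), "hubB", paste0("b", 1:3)))
  h2 <- hub_genes(star2, part2, centrality = "degree", top_k = 1)
  expect_setequal(h2$merged, c("hubA", "hubB"))
  # go intersection is returned separately
  h3 <- hub_genes(star2, part2, centrality = "degree", top_k = 1,
                  go_genes = c("hubA", "a1"))
  expect_equal(h3$go_intersection, "hubA")
  # tie-break on a cycle: lexicographically smallest id
  cyc <- reduce_edges(data.frame(source = c("x", "y", "z"),
                                 target = c("y", "z", "x")))$graph
  partc <- setNames(rep(1L, 3), c("x", "y", "z"))
  hc <- hub_genes(cyc, partc, centrality = "degree", top_k = 1)
  expect_equal(hc$per_module[["1"]], "x")
  # small module: all nodes returned and flagged
  h4 <- hub_genes(cyc, partc, centrality = "degree", top_k = 10)
  expect_setequal(h4$per_module[["1"]], c("x", "y", "z"))
  expect_equal(h4$flagged_modules, 1L)
})

test_that("module coloring is deterministic and complete", {
  g <- reduce_edges(data.frame(source = c("a", "b", "c"),
                               target = c("b", "c", "d")))$graph
  part <- setNames(c(1L, 1L, 2L), c("a", "b", "c"))  # d unassigned
  g1 <- module_colored_graph(g, part)
  cols <- igraph::V(g1)$color
  names(cols) <- igraph::V(g1)$name
  expect_equal(unname(cols["d"]), "grey")
  expect_length(unique(cols[c("a", "b", "c")]), 2)
  g2 <- module_colored_graph(g, part)
  expect_identical(igraph::V(g2)$color, igraph::V(g1)$color)
  # empty partition: everything unassigned
  g3 <- module_colored_graph(g, setNames(integer(), character()))
  expect_true(all(igraph::V(g3)$color == "grey"))
})

test_that("correlation module graphs respect threshold structure", {
  # planted 2-block similarity
  n <- 20
  S <- matrix(0.2, n, n)
  S[1:10, 1:10] <- 0.9
  S[11:20, 11:20] <- 0.9
  diag(S) <- 1
  ids <- sprintf("g%02d", 1:n)
  dimnames(S) <- list(ids, ids)
  part <- setNames(rep(1:2, each = 10), ids)
  g <- correlation_module_graph(S, part, modules = 1:2, threshold = 0.5)
  expect_equal(igraph::ecount(g), 2 * choose(10, 2))  # two near-cliques
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)  # no cross edges
  # threshold 0: complete graph on selected genes
  g0 <- correlation_module_graph(S, part, modules = 1, threshold = 0)
  expect_equal(igraph::ecount(g0), choose(10, 2))
  # edge weights carry the similarity
  expect_true(all(igraph::E(g)$weight == 0.9))
  expect_error(correlation_module_graph(S, part, 1, threshold = 2),
               class = "rnanet_validation_error")
  expect_error(correlation_module_graph(S, part, 9, threshold = 0.5),
               class = "rnanet_validation_error")
})

test_that("GraphML round-trips node and edge attributes", {
  dir <- withr::local_tempdir()
  g <- reduce_edges(data.frame(source = c("a", "b"),
                               target = c("b", "c")))$graph
  igraph::V(g)$effect <- c(1.5, -2, 0.25)
  igraph::V(g)$mean_count <- c(3, 8, 1)
  g <- encode_visual_attributes(g)
  path <- file.path(dir, "net.graphml")
  write_graphml(g, path)
  g2 <- read_graphml(path)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  idx <- match(igraph::V(g)$name, igraph::V(g2)$name)
  expect_equal(igraph::V(g2)$effect[idx], igraph::V(g)$effect)
  expect_equal(igraph::V(g2)$opacity[idx], igraph::V(g)$opacity)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
})
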