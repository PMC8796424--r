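make_toy_obo <- function(dir) {
  path <- file.path(dir, "toy.obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: child1",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: child2",
    "namespace: biological_process", "is_a: GO:0000001 ! root",
    "alt_id: GO:0999999", "",
    "[Term]", "id: GO:0000004", "name: grandchild1",
    "namespace: biological_process", "is_a: GO:0000002 ! child1", "",
    "[Term]", "id: GO:0000005", "name: grandchild2",
    "namespace: biological_process", "is_a: GO:0000002 ! child1",
    "relationship: part_of GO:0000003 ! child2", ""), path)
  path
}

test_that("OBO parsing builds the expected DAG and handles obsoletes", {
  dir <- withr::local_tempdir()
  dag <- load_obo(make_toy_obo(dir))
  expect_equal(nrow(dag$terms), 5)
  expect_equal(nrow(dag$edges), 5)  # 4 is_a + 1 part_of
  expect_equal(dag$roots, "GO:0000001")
  expect_equal(unname(dag$alt_ids["GO:0999999"]), "GO:0000003")

  # obsolete terms are excluded and counted
  obs <- file.path(dir, "obs.obo")
  writeLines(c("[Term]", "id: GO:0000001", "name: root", "",
               "[Term]", "id: GO:0000002", "name: dead",
               "is_a: GO:0000001", "is_obsolete: true", ""), obs)
  dag2 <- load_obo(obs)
  expect_equal(nrow(dag2$terms), 1)
  expect_equal(dag2$n_obsolete, 1L)

  # a cycle is fatal and names a member
  cyc <- file.path(dir, "cycle.obo")
  writeLines(c("[Term]", "id: GO:0000001", "is_a: GO:0000002", "",
               "[Term]", "id: GO:0000002", "is_a: GO:0000001", ""), cyc)
  err <- expect_error(load_obo(cyc), class = "rnanet_validation_error")
  expect_match(conditionMessage(err), "GO:000000")
})

test_that("annotation propagation equals the reachability oracle", {
  dir <- withr::local_tempdir()
  dag <- load_obo(make_toy_obo(dir))
  direct <- list(gA = "GO:0000005", gB = "GO:0000001",
                 gC = c("GO:0000004", "GO:0999999"), gD = "GO:0000042")
  ann <- propagate_annotations(dag, direct)
  # leaf annotation reaches the root through both is_a and part_of
  expect_setequal(ann$propagated$gA,
                  c("GO:0000005", "GO:0000002", "GO:0000003", "GO:0000001"))
  # root-only annotation is a fixed point
  expect_equal(ann$propagated$gB, "GO:0000001")
  # alt_id resolved before propagation
  expect_true("GO:0000003" %in% ann$direct$gC)
  # unknown term in rejects
  expect_equal(ann$rejects$term, "GO:0000042")

  # closure property: every ancestor of a propagated term is present
  for (g in names(ann$propagated))
    for (t in ann$propagated[[g]])
      expect_true(all(term_ancestors(dag, t) %in% ann$propagated[[g]]))

  # idempotence: propagating the propagated sets changes nothing
  ann2 <- propagate_annotations(dag, ann$propagated)
  expect_equal(ann2$propagated[order(names(ann2$propagated))],
               ann$propagated[order(names(ann$propagated))])

  # random-DAG oracle: igraph reachability
  set.seed(3)
  n <- 15
  edges <- data.frame(child = paste0("T", 2:n),
                      parent = paste0("T", vapply(2:n, function(i)
                        sample(seq_len(i - 1), 1), 1L)))
  obo <- file.path(dir, "rand.obo")
  writeLines(unlist(lapply(seq_len(n), function(i) c(
    "[Term]", paste0("id: T", i),
    if (i > 1) paste0("is_a: ",
                      edges$parent[match(paste0("T", i), edges$child)]),
    ""))), obo)
  rdag <- load_obo(obo)
  g <- igraph::graph_from_data_frame(rdag$edges)
  for (t in paste0("T", c(5, 9, 15))) {
    reach <- setdiff(names(igraph::subcomponent(g, t, mode = "out")), t)
    expect_setequal(term_ancestors(rdag, t), reach)
  }
})

test_that("KS statistic and p-value agree with a permutation oracle", {
  dir <- withr::local_tempdir()
  dag <- load_obo(make_toy_obo(dir))
  # 4 term genes hold the 4 smallest of 12 scores
  genes <- sprintf("g%02d", 1:12)
  scores <- setNames(seq(0.01, 0.9, length.out = 12), genes)
  direct <- c(setNames(rep(list("GO:0000002"), 4), genes[1:4]),
              setNames(rep(list("GO:0000003"), 8), genes[5:12]))
  ann <- propagate_annotations(dag, direct)
  res <- ks_enrichment(scores, ann, min_annotated = 2)
  row <- res[res$term == "GO:0000002", ]
  # term genes strictly below the complement: maximal separation
  expect_equal(row$ks_statistic, 1)
  # permutation oracle for the p-value of the observed D
  D_obs <- row$ks_statistic
  combn_idx <- utils::combn(12, 4)
  D_perm <- apply(combn_idx, 2, function(ix)
    suppressWarnings(stats::ks.test(scores[ix], scores[-ix],
                                    alternative = "greater")$statistic))
  expect_equal(row$p_value, mean(D_perm >= D_obs - 1e-12),
               tolerance = 1e-6)
  # the root covers every gene and is skipped with a flag
  expect_false("GO:0000001" %in% res$term)
  expect_true("GO:0000001" %in% attr(res, "skipped"))
})

test_that("KS enrichment is antisymmetric under score negation", {
  set.seed(17)
  genes <- sprintf("g%02d", 1:20)
  scores <- setNames(runif(20), genes)
  x <- scores[1:6]; y <- scores[7:20]
  p_fwd <- suppressWarnings(
    stats::ks.test(x, y, alternative = "greater")$p.value)
  p_rev <- suppressWarnings(
    stats::ks.test(-x, -y, alternative = "less")$p.value)
  expect_equal(p_fwd, p_rev, tolerance = 1e-12)
})

test_that("a planted enriched term outranks decoys", {
  hits <- 0L
  for (s in 1:5) {
    spec <- simulation_spec(n_genes = 300, n_deg = 60, go_terms = 21,
                            seed = s)
    sim <- simulate_counts(spec)
    ann_data <- simulate_annotations(spec, sim$truth)
    obo <- withr::local_tempfile(fileext = ".obo")
    writeLines(ann_data$obo_lines, obo)
    dag <- load_obo(obo)
    direct <- split(ann_data$annotations$term_id,
                    ann_data$annotations$gene_id)
    ann <- propagate_annotations(dag, direct)
    deg_tab <- simulate_deg_table(spec, sim$truth)
    scores <- setNames(deg_tab$PValue, deg_tab$gene_id)
    res <- ks_enrichment(scores, ann, min_annotated = 10)
    leaves <- res[res$annotated_count <= spec$genes_per_term, ]
    if (leaves$term[1] == ann_data$planted_term) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("top significant genes honor ties and truncation", {
  dir <- withr::local_tempdir()
  dag <- load_obo(make_toy_obo(dir))
  genes <- sprintf("g%02d", 1:12)
  direct <- c(setNames(rep(list("GO:0000004"), 4), genes[1:4]),
              setNames(rep(list("GO:0000005"), 4), genes[5:8]),
              setNames(rep(list("GO:0000003"), 4), genes[9:12]))
  ann <- propagate_annotations(dag, direct)
  scores <- setNames(c(rep(0.01, 4), rep(0.02, 4), rep(0.9, 4)), genes)
  res <- ks_enrichment(scores, ann, min_annotated = 2)
  top1 <- top_significant_genes(res, ann, k_terms = 1)
  expect_setequal(top1, ann$genes_per_term[[res$term[1]]])
  # k larger than available: all terms used, flagged
  all_genes <- top_significant_genes(res, ann, k_terms = 100)
  expect_true(attr(all_genes, "truncated"))
  expect_setequal(attr(all_genes, "terms_used"), res$term)
})
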