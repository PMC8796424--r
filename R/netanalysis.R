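## Graph analytics on DEG networks: edge-list reduction, DEG overlap,
## per-gene effect summaries, visual attribute encoding, classical graph
## metrics, hub extraction and module coloring. Graphs are igraph objects
## with gene ids as vertex names.

#' Read a source-target edge list
#' @param path Tab-separated file with columns source, target and an
#'   optional third weight column; a header row is detected and skipped.
#' @return data.frame with `source`, `target` (and `weight` if present).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) rn_io_error("edge list not found: %s", path)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- all(tolower(first[1:2]) %in%
                    c("source", "target", "from", "to", "gene1", "gene2"))
  tab <- utils::read.delim(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  names(tab)[1:2] <- c("source", "target")
  if (ncol(tab) >= 3) names(tab)[3] <- "weight"
  tab[1:min(3, ncol(tab))]
}

#' Reduce a raw edge list to a simple undirected graph
#'
#' Collapses duplicate and reversed-duplicate rows to single undirected
#' edges and (by default) drops self-loops; malformed rows (empty tokens)
#' go to a rejects report.
#'
#' @param raw_edges data.frame with `source` and `target` columns (e.g. from
#'   [read_edge_list()]).
#' @param keep_self_loops Keep self-loops instead of dropping them.
#' @return List with `graph` (simple undirected igraph) and `report`
#'   (input_rows, kept_edges, dropped_self_loops, rejected_rows, rejects).
#' @export
reduce_edges <- function(raw_edges, keep_self_loops = FALSE) {
  src <- trimws(as.character(raw_edges$source))
  tgt <- trimws(as.character(raw_edges$target))
  bad <- !nzchar(src) | !nzchar(tgt) | is.na(src) | is.na(tgt)
  rejects <- raw_edges[bad, , drop = FALSE]
  src <- src[!bad]; tgt <- tgt[!bad]
  loops <- src == tgt
  n_loops <- sum(loops)
  if (!keep_self_loops) {
    src <- src[!loops]; tgt <- tgt[!loops]
  }
  a <- pmin(src, tgt); b <- pmax(src, tgt)   # canonical unordered pair
  keep <- !duplicated(paste(a, b, sep = "\r"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE)
  list(graph = g,
       report = list(input_rows = nrow(raw_edges),
                     kept_edges = igraph::ecount(g),
                     dropped_self_loops = if (keep_self_loops) 0L else n_loops,
                     rejected_rows = sum(bad),
                     rejects = rejects))
}

#' Overlap a network with a DEG table
#'
#' Induces the subgraph on nodes that are differentially expressed and
#' attaches per-gene `effect` and `mean_count` vertex attributes (isoform
#' rows are averaged via [gene_effect_summary()]).
#'
#' @param graph Reduced igraph network.
#' @param deg DEG table (see [read_deg_table()]); ids may be transcript ids
#'   whose `.<integer>` suffix is stripped for matching.
#' @return igraph subgraph; attribute `empty_overlap` is TRUE when no node
#'   is differentially expressed.
#' @export
overlap_deg <- function(graph, deg) {
  gene <- sub("\\.\\d+$", "", deg$id)
  nodes <- intersect(igraph::V(graph)$name, unique(gene))
  sub <- igraph::induced_subgraph(graph, nodes)
  if (length(nodes) == 0) {
    attr(sub, "empty_overlap") <- TRUE
    return(sub)
  }
  summ <- do.call(rbind, lapply(nodes, function(g0) {
    s <- gene_effect_summary(deg[gene == g0, , drop = FALSE])
    data.frame(gene = g0, effect = s$effect, mean_count = s$mean_count,
               sign_conflict = s$sign_conflict, stringsAsFactors = FALSE)
  }))
  idx <- match(igraph::V(sub)$name, summ$gene)
  igraph::V(sub)$effect <- summ$effect[idx]
  igraph::V(sub)$mean_count <- summ$mean_count[idx]
  igraph::V(sub)$sign_conflict <- summ$sign_conflict[idx]
  attr(sub, "empty_overlap") <- FALSE
  sub
}

#' Summarize a gene's isoform-level effects
#'
#' Arithmetic mean of isoform effect sizes and mean counts; flags genes
#' whose isoforms disagree in effect sign.
#'
#' @param deg_rows DEG-table rows belonging to one gene.
#' @return List with `effect`, `mean_count`, `sign_conflict`.
#' @export
gene_effect_summary <- function(deg_rows) {
  if (nrow(deg_rows) == 0)
    rn_validation_error("gene_effect_summary needs at least one row")
  eff <- deg_rows$effect
  list(effect = mean(eff),
       mean_count = mean(deg_rows$mean_count),
       sign_conflict = length(unique(sign(eff[eff != 0]))) > 1)
}

#' Encode visual attributes on a DEG network
#'
#' Shape encodes the sign of the effect (`"up"` / `"down"` / `"zero"`), size
#' is the mean count min-max scaled to `size_range`, and opacity is the
#' absolute effect min-max scaled to `[0, 1]` (1 everywhere when all effects
#' are equal).
#'
#' @param graph igraph with `effect` and `mean_count` vertex attributes.
#' @param size_range Two-element numeric range for node sizes.
#' @return The graph with `shape`, `size`, `opacity` vertex attributes.
#' @export
encode_visual_attributes <- function(graph, size_range = c(2, 10)) {
  eff <- igraph::V(graph)$effect
  mc <- igraph::V(graph)$mean_count
  if (is.null(eff) || is.null(mc))
    rn_validation_error("graph lacks 'effect'/'mean_count' attributes")
  rescale <- function(x, lo, hi) {
    if (length(x) == 0) return(numeric())
    rng <- range(x, finite = TRUE)
    if (diff(rng) == 0) return(rep(hi, length(x)))
    lo + (x - rng[1]) / diff(rng) * (hi - lo)
  }
  igraph::V(graph)$shape <- c("down", "zero", "up")[sign(eff) + 2]
  igraph::V(graph)$size <- rescale(mc, size_range[1], size_range[2])
  igraph::V(graph)$opacity <- rescale(abs(eff), 0, 1)
  graph
}

#' Classical graph metrics
#'
#' Per node: degree, betweenness (unweighted shortest paths), closeness
#' (reciprocal of the summed distance to reachable vertices), eigenvector
#' centrality. Global: diameter per connected component, mean local
#' clustering coefficient (isolated/degree-1 nodes counted as 0) and
#' component count.
#'
#' @param graph Reduced igraph network.
#' @return A `network_metrics` list: `nodes` (data.frame), `diameter_per_component`,
#'   `mean_clustering`, `components`.
#' @export
compute_metrics <- function(graph) {
  if (igraph::vcount(graph) == 0)
    rn_validation_error("cannot compute metrics of an empty graph")
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, weights = NA)
  cls <- suppressWarnings(igraph::closeness(graph, weights = NA, mode = "all"))
  eig <- igraph::eigen_centrality(graph, weights = NA)$vector
  comp <- igraph::components(graph)
  diam <- vapply(seq_len(comp$no), function(i) {
    sub <- igraph::induced_subgraph(graph, which(comp$membership == i))
    igraph::diameter(sub, weights = NA)
  }, numeric(1))
  cc <- igraph::transitivity(graph, type = "localundirected", isolates = "zero")
  structure(list(
    nodes = data.frame(gene = igraph::V(graph)$name, degree = deg,
                       betweenness = btw, closeness = cls,
                       eigenvector = eig, row.names = NULL,
                       stringsAsFactors = FALSE),
    diameter_per_component = diam,
    mean_clustering = mean(cc),
    components = comp$no), class = "network_metrics")
}

.centrality_fun <- function(graph, centrality) {
  switch(centrality,
         degree = igraph::degree(graph),
         betweenness = igraph::betweenness(graph, weights = NA),
         eigenvector = igraph::eigen_centrality(graph, weights = NA)$vector,
         rn_validation_error("unknown centrality '%s'", centrality))
}

#' Hub genes per module
#'
#' Within each module's induced subgraph, ranks nodes by the chosen
#' centrality and keeps the top `top_k` (ties broken by descending
#' centrality then ascending gene id); modules smaller than `top_k`
#' contribute all their nodes and are flagged. The per-module hub lists are
#' merged and intersected with a significant-GO gene set.
#'
#' @param graph Reduced igraph network.
#' @param partition Module partition covering the graph nodes (label 0 =
#'   unassigned, skipped).
#' @param centrality `"eigenvector"` (default), `"degree"` or
#'   `"betweenness"`.
#' @param top_k Hubs kept per module.
#' @param go_genes Character vector of significant-GO genes (may be empty).
#' @return List with `per_module` (label -> hub ids), `merged` (union),
#'   `go_intersection`, `flagged_modules` (smaller than `top_k`).
#' @export
hub_genes <- function(graph, partition,
                      centrality = c("eigenvector", "degree", "betweenness"),
                      top_k = 5, go_genes = character()) {
  centrality <- match.arg(centrality)
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  labels <- sort(setdiff(unique(assignment[igraph::V(graph)$name]), c(0L, NA)))
  per_module <- list(); flagged <- integer()
  for (l in labels) {
    genes <- intersect(igraph::V(graph)$name,
                       names(assignment)[assignment == l])
    sub <- igraph::induced_subgraph(graph, genes)
    sc <- .centrality_fun(sub, centrality)
    ord <- order(-sc, names(sc))
    if (length(genes) <= top_k) flagged <- c(flagged, l)
    per_module[[as.character(l)]] <- names(sc)[utils::head(ord, top_k)]
  }
  merged <- sort(unique(unlist(per_module)))
  list(per_module = per_module, merged = merged,
       go_intersection = intersect(merged, go_genes),
       flagged_modules = flagged)
}

#' Color graph nodes by module membership
#'
#' Assigns each node the (deterministic, label-indexed) color of its module;
#' nodes without a module get the unassigned color.
#'
#' @param graph igraph network.
#' @param partition Module partition.
#' @param unassigned_color Color for unassigned/unknown nodes.
#' @return Graph with `module` and `color` vertex attributes.
#' @export
module_colored_graph <- function(graph, partition,
                                 unassigned_color = "grey") {
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  labels <- sort(setdiff(unique(assignment), 0L))
  palette <- grDevices::hcl.colors(max(length(labels), 1L), "Dark 3")
  mod <- assignment[igraph::V(graph)$name]
  mod[is.na(mod)] <- 0L
  igraph::V(graph)$module <- as.integer(mod)
  igraph::V(graph)$color <- ifelse(mod == 0L, unassigned_color,
                                   palette[match(mod, labels)])
  graph
}

#' Correlation graph over selected modules
#'
#' Builds the thresholded correlation network over the genes of the chosen
#' modules: edges where similarity `s_ij >= threshold`, weighted by `s_ij`,
#' with node size proportional to degree.
#'
#' @param S Similarity matrix (named rows/columns).
#' @param partition Module partition.
#' @param modules Module labels to include.
#' @param threshold Correlation threshold in `[0, 1]`.
#' @return igraph with edge `weight` and vertex `module`, `size` attributes.
#' @export
correlation_module_graph <- function(S, partition, modules, threshold) {
  if (threshold < 0 || threshold > 1)
    rn_validation_error("threshold must lie in [0,1], got %g", threshold)
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  unknown <- setdiff(modules, assignment)
  if (length(unknown) > 0)
    rn_validation_error("unknown module label(s): %s",
                        paste(unknown, collapse = ", "))
  genes <- names(assignment)[assignment %in% modules]
  genes <- intersect(rownames(S), genes)
  sub <- S[genes, genes, drop = FALSE]
  adj <- (sub >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(g)
  igraph::E(g)$weight <- sub[cbind(ends[, 1], ends[, 2])]
  igraph::V(g)$module <- as.integer(assignment[igraph::V(g)$name])
  dg <- igraph::degree(g)
  igraph::V(g)$size <- if (max(dg) > 0) dg / max(dg) else dg
  g
}

#' Write a graph with all attributes as GraphML
#' @param graph igraph object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file
#' @param path GraphML path.
#' @return igraph object with attributes restored.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) rn_io_error("GraphML file not found: %s", path)
  igraph::read_graph(path, format = "graphml")
}
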