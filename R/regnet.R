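## Bipartite TF-gene regulatory networks: correlation-predicted edges
## thresholded on biweight midcorrelation, and regulator path tables
## (DREM output) converted through an incidence matrix.

#' Read a transcription-factor table
#' @param path 2-column tab-separated file (tf_id, family), AtTFDB-style.
#' @return data.frame with `tf_id`, `family`; tf_id unique.
#' @export
read_tf_table <- function(path) {
  tab <- read_tsv_table(path, colClasses = "character")
  if (ncol(tab) < 2)
    rn_parse_error("TF table needs 2 columns (tf_id, family)")
  names(tab)[1:2] <- c("tf_id", "family")
  if (anyDuplicated(tab$tf_id))
    rn_validation_error("duplicate tf_id(s): %s",
                        paste(unique(tab$tf_id[duplicated(tab$tf_id)]),
                              collapse = ", "))
  tab[1:2]
}

.new_regnet <- function(tf_set, gene_set, edges, provenance) {
  # bipartiteness assertion: runs on every construction
  if (length(intersect(tf_set, gene_set)) > 0)
    rn_validation_error("TF and gene sides overlap: %s",
                        paste(utils::head(intersect(tf_set, gene_set), 5),
                              collapse = ", "))
  if (nrow(edges) > 0 &&
      (!all(edges$tf %in% tf_set) || !all(edges$gene %in% gene_set)))
    rn_validation_error("edge endpoints outside the declared node sets")
  structure(list(tf_set = sort(tf_set), gene_set = sort(gene_set),
                 edges = edges, provenance = provenance),
            class = "bipartite_regnet")
}

#' Incidence matrix of a bipartite regulatory network
#' @param net A `bipartite_regnet`.
#' @return TF-by-gene matrix; weighted where edge weights exist, else 0/1.
#' @export
regnet_incidence <- function(net) {
  B <- matrix(0, nrow = length(net$tf_set), ncol = length(net$gene_set),
              dimnames = list(net$tf_set, net$gene_set))
  if (nrow(net$edges) > 0) {
    w <- if ("weight" %in% names(net$edges)) net$edges$weight else 1
    B[cbind(net$edges$tf, net$edges$gene)] <- w
  }
  B
}

#' Build a bipartite regulatory network from an incidence matrix
#' @param B TF-by-gene incidence matrix (rownames = TFs, colnames = genes);
#'   nonzero cells become edges with the cell value as weight.
#' @param provenance Edge provenance label (`"predicted"` or `"drem"`).
#' @return A `bipartite_regnet`.
#' @export
regnet_from_incidence <- function(B, provenance = "drem") {
  nz <- which(B != 0, arr.ind = TRUE)
  edges <- data.frame(tf = rownames(B)[nz[, 1]],
                      gene = colnames(B)[nz[, 2]],
                      weight = B[nz],
                      provenance = provenance,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  .new_regnet(rownames(B), colnames(B), edges, provenance)
}

#' Predict a regulatory network from expression correlation
#'
#' Connects a transcription factor `t` to a significant gene `g` whenever
#' `|bicor(x_t, x_g)| >= tau`, with the signed biweight midcorrelation kept
#' as the edge weight (sign hints at activation vs repression). A TF that is
#' itself a significant gene stays on the TF side only, preserving
#' bipartiteness. TFs absent from the expression matrix are reported, not
#' fatal, unless none is present.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param tfs TF table (see [read_tf_table()]) or character vector of TF ids.
#' @param significant_genes Character vector of significant gene ids.
#' @param tau Absolute-correlation threshold in `(0, 1]`.
#' @return A `bipartite_regnet` with provenance `"predicted"`; attribute
#'   `missing_tfs` lists TFs not found in `expr`.
#' @export
predicted_regulatory_network <- function(expr, tfs, significant_genes, tau) {
  if (tau <= 0 || tau > 1)
    rn_validation_error("tau must lie in (0,1], got %g", tau)
  tf_ids <- if (is.data.frame(tfs)) tfs$tf_id else as.character(tfs)
  present <- intersect(tf_ids, rownames(expr))
  missing_tfs <- setdiff(tf_ids, present)
  if (length(present) == 0)
    rn_validation_error("no TF found in the expression matrix")
  genes <- setdiff(intersect(significant_genes, rownames(expr)), tf_ids)
  edges <- data.frame(tf = character(), gene = character(),
                      weight = numeric(), provenance = character(),
                      stringsAsFactors = FALSE)
  if (length(genes) > 0) {
    R <- .bicor_matrix(expr[present, , drop = FALSE],
                       expr[genes, , drop = FALSE])
    dimnames(R) <- list(present, genes)
    hit <- which(abs(R) >= tau, arr.ind = TRUE)
    if (nrow(hit) > 0)
      edges <- data.frame(tf = present[hit[, 1]], gene = genes[hit[, 2]],
                          weight = R[hit], provenance = "predicted",
                          stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  net <- .new_regnet(present, genes, edges, "predicted")
  attr(net, "missing_tfs") <- missing_tfs
  net
}

#' Parse regulator path tables from a directory
#'
#' Collects the per-path gene tables written after regulatory-path
#' inference: every file whose name contains the literal token `path` is
#' one path. Each table must have a `gene` column; its regulators come
#' either from in-table `tf` (and optional `score`) columns or from a
#' sidecar file `<stem>_regulators.tsv` with columns `tf`, `score`.
#'
#' @param dir Directory holding the path files.
#' @return A `drem_path_table`: list of records with `label`, `genes`,
#'   `regulators` (data.frame tf/score).
#' @export
parse_drem_tables <- function(dir) {
  if (!dir.exists(dir)) rn_io_error("path-table directory not found: %s", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[grepl("path", basename(files), ignore.case = TRUE) &
                 !grepl("_regulators\\.", basename(files))]
  if (length(files) == 0)
    rn_io_error("no files containing a 'path' token under %s", dir)
  records <- lapply(files, function(f) {
    stem <- tools::file_path_sans_ext(basename(f))
    tab <- read_tsv_table(f)
    if (!"gene" %in% names(tab))
      rn_parse_error("path table '%s' lacks a 'gene' column", basename(f))
    if ("tf" %in% names(tab)) {
      reg <- unique(data.frame(
        tf = as.character(tab$tf[!is.na(tab$tf) & nzchar(tab$tf)]),
        score = if ("score" %in% names(tab))
          as.numeric(tab$score[!is.na(tab$tf) & nzchar(tab$tf)]) else NA_real_,
        stringsAsFactors = FALSE))
    } else {
      sidecar <- file.path(dir, paste0(stem, "_regulators.tsv"))
      reg <- if (file.exists(sidecar)) {
        rt <- read_tsv_table(sidecar)
        data.frame(tf = as.character(rt$tf),
                   score = if ("score" %in% names(rt))
                     as.numeric(rt$score) else NA_real_,
                   stringsAsFactors = FALSE)
      } else data.frame(tf = character(), score = numeric(),
                        stringsAsFactors = FALSE)
    }
    list(label = stem, genes = unique(as.character(tab$gene)),
         regulators = reg)
  })
  labels <- vapply(records, `[[`, "", "label")
  if (anyDuplicated(labels))
    rn_validation_error("duplicate path label(s): %s",
                        paste(unique(labels[duplicated(labels)]),
                              collapse = ", "))
  structure(stats::setNames(records, labels), class = "drem_path_table")
}

#' Bipartite network from regulator path tables
#'
#' Sets `B[t, g] = 1` whenever TF `t` regulates a path containing gene `g`
#' (optionally restricted to a DEG set), then builds the bipartite graph
#' from the incidence matrix.
#'
#' @param paths A [parse_drem_tables()] result.
#' @param deg Optional character vector restricting the gene side.
#' @return A `bipartite_regnet` with provenance `"drem"`.
#' @export
drem_bipartite <- function(paths, deg = NULL) {
  if (length(paths) == 0) rn_validation_error("no paths supplied")
  tfs <- sort(unique(unlist(lapply(paths, function(p) p$regulators$tf))))
  genes <- sort(unique(unlist(lapply(paths, `[[`, "genes"))))
  if (!is.null(deg)) genes <- intersect(genes, deg)
  genes <- setdiff(genes, tfs)
  B <- matrix(0, nrow = length(tfs), ncol = length(genes),
              dimnames = list(tfs, genes))
  for (p in paths) {
    g <- intersect(p$genes, genes)
    t <- intersect(p$regulators$tf, tfs)
    B[t, g] <- 1
  }
  regnet_from_incidence(B, provenance = "drem")
}

#' Merge two bipartite regulatory networks
#'
#' Union of node sets and edges; an edge present in both inputs keeps both
#' provenance labels (comma-joined).
#'
#' @param a,b `bipartite_regnet` objects.
#' @return Merged `bipartite_regnet`.
#' @export
merge_regulatory_networks <- function(a, b) {
  tf_set <- union(a$tf_set, b$tf_set)
  gene_set <- setdiff(union(a$gene_set, b$gene_set), tf_set)
  all_edges <- rbind(a$edges, b$edges)
  all_edges <- all_edges[all_edges$gene %in% gene_set, , drop = FALSE]
  key <- paste(all_edges$tf, all_edges$gene, sep = "\r")
  merged <- lapply(split(seq_len(nrow(all_edges)), key), function(ix) {
    rows <- all_edges[ix, , drop = FALSE]
    data.frame(tf = rows$tf[1], gene = rows$gene[1],
               weight = rows$weight[1],
               provenance = paste(sort(unique(rows$provenance)),
                                  collapse = ","),
               stringsAsFactors = FALSE)
  })
  edges <- if (length(merged)) do.call(rbind, merged) else
    data.frame(tf = character(), gene = character(), weight = numeric(),
               provenance = character(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  .new_regnet(tf_set, gene_set, edges,
              paste(sort(unique(c(a$provenance, b$provenance))),
                    collapse = ","))
}

#' Convert a bipartite regulatory network to an igraph object
#'
#' Vertices carry a `side` attribute (`"TF"` or `"gene"`) and a bipartite
#' `type`; edges keep `weight` and `provenance`. Optional layout
#' coordinates (`"tree"` = Reingold-Tilford, `"circle"`) are stored as `x`,
#' `y` vertex attributes.
#'
#' @param net A `bipartite_regnet`.
#' @param layout `"none"`, `"tree"` or `"circle"`.
#' @return igraph object.
#' @export
regnet_to_igraph <- function(net, layout = c("none", "tree", "circle")) {
  layout <- match.arg(layout)
  vertices <- data.frame(
    name = c(net$tf_set, net$gene_set),
    side = c(rep("TF", length(net$tf_set)),
             rep("gene", length(net$gene_set))),
    stringsAsFactors = FALSE)
  edges <- net$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$tf, to = edges$gene,
               weight = edges$weight, provenance = edges$provenance,
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = vertices)
  igraph::V(g)$type <- igraph::V(g)$side == "gene"
  if (layout != "none") {
    xy <- switch(layout,
                 tree = igraph::layout_as_tree(g),
                 circle = igraph::layout_in_circle(g))
    igraph::V(g)$x <- xy[, 1]
    igraph::V(g)$y <- xy[, 2]
  }
  g
}
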