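## Gene ontology enrichment: OBO 1.2 parsing into a DAG, true-path
## propagation of annotations, and Kolmogorov-Smirnov enrichment of
## gene-level scores per term.

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas, skipping obsolete terms, resolving `alt_id`
#' aliases to their canonical term, and collecting `is_a` plus
#' `relationship: part_of` edges (child -> parent). The result must be
#' acyclic.
#'
#' @param path Path to the `.obo` file.
#' @return An `ontology_dag` list: `terms` (data.frame id/name/namespace),
#'   `edges` (data.frame child/parent), `alt_ids` (named vector alias ->
#'   canonical), `roots` (ids without parents), `n_obsolete`.
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) rn_io_error("OBO file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  terms <- list(); edges <- list(); alt <- character(); n_obsolete <- 0L
  for (s in term_starts) {
    nxt <- starts[starts > s]
    block <- lines[(s + 1):(if (length(nxt)) nxt[1] - 1 else length(lines))]
    field <- function(key) sub(paste0("^", key, ":\\s*"), "",
                               grep(paste0("^", key, ":"), block, value = TRUE))
    if (any(grepl("^is_obsolete:\\s*true", block))) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    id <- field("id")[1]
    if (is.na(id) || !nzchar(id)) next
    terms[[id]] <- data.frame(
      id = id,
      name = field("name")[1] %||% NA_character_,
      namespace = field("namespace")[1] %||% NA_character_,
      stringsAsFactors = FALSE)
    for (a in field("alt_id")) alt[a] <- id
    parents <- sub("\\s*!.*$", "", field("is_a"))
    rel <- field("relationship")
    part_of <- sub("\\s*!.*$", "", sub("^part_of\\s+", "",
                                       grep("^part_of\\s", rel, value = TRUE)))
    for (p in c(parents, part_of))
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = p,
                                                stringsAsFactors = FALSE)
  }
  term_df <- do.call(rbind, terms)
  rownames(term_df) <- NULL
  edge_df <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)
  # edges may point at obsolete/unknown parents; drop those quietly
  edge_df <- edge_df[edge_df$parent %in% term_df$id &
                     edge_df$child %in% term_df$id, , drop = FALSE]
  if (nrow(edge_df) > 0) {
    g <- igraph::graph_from_data_frame(edge_df, directed = TRUE,
                                       vertices = term_df$id)
    if (!igraph::is_dag(g)) {
      sc <- igraph::components(g, mode = "strong")
      big <- which(sc$csize > 1)[1]
      cyc <- names(sc$membership)[sc$membership == big][1]
      rn_validation_error("ontology contains a cycle through term '%s'", cyc)
    }
  }
  parents_list <- split(edge_df$parent, edge_df$child)
  roots <- setdiff(term_df$id, edge_df$child)
  structure(list(terms = term_df, edges = edge_df, alt_ids = alt,
                 parents = parents_list, roots = roots,
                 n_obsolete = n_obsolete),
            class = "ontology_dag")
}

#' Ancestors of a term
#' @param dag An [load_obo()] result.
#' @param term Term id (alt_ids resolved).
#' @return Character vector of all ancestors (excluding the term itself).
#' @export
term_ancestors <- function(dag, term) {
  if (term %in% names(dag$alt_ids)) term <- dag$alt_ids[[term]]
  seen <- character()
  frontier <- dag$parents[[term]] %||% character()
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
  }
  seen
}

#' Propagate gene annotations up the ontology (true-path rule)
#'
#' Extends each gene's direct annotations with all ancestors of each
#' annotated term, so that annotation to a term implies annotation to every
#' term above it. Idempotent. Annotations to unknown terms are collected in
#' a rejects report.
#'
#' @param dag An [load_obo()] result.
#' @param direct Named list gene -> character vector of term ids (alt_ids
#'   accepted).
#' @return A `gene_annotation` list: `direct`, `propagated` (both gene ->
#'   terms), `genes_per_term` (term -> genes, propagated), `rejects`
#'   (data.frame gene/term of unknown annotations).
#' @export
propagate_annotations <- function(dag, direct) {
  known <- dag$terms$id
  anc_cache <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    a <- term_ancestors(dag, t)
    anc_cache[[t]] <- a
    a
  }
  rejects <- list()
  prop <- list(); dirc <- list()
  for (g in names(direct)) {
    terms <- unique(as.character(direct[[g]]))
    is_alt <- terms %in% names(dag$alt_ids)
    terms[is_alt] <- dag$alt_ids[terms[is_alt]]
    bad <- setdiff(terms, known)
    if (length(bad) > 0)
      rejects[[g]] <- data.frame(gene = g, term = bad,
                                 stringsAsFactors = FALSE)
    terms <- intersect(terms, known)
    if (length(terms) == 0) next
    dirc[[g]] <- terms
    prop[[g]] <- union(terms, unique(unlist(lapply(terms, get_anc))))
  }
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(gene = character(), term = character(),
               stringsAsFactors = FALSE)
  rownames(rejects) <- NULL
  genes_per_term <- list()
  for (g in names(prop))
    for (t in prop[[g]]) genes_per_term[[t]] <- c(genes_per_term[[t]], g)
  structure(list(direct = dirc, propagated = prop,
                 genes_per_term = genes_per_term, rejects = rejects),
            class = "gene_annotation")
}

#' Kolmogorov-Smirnov GO enrichment
#'
#' For each term with at least `min_annotated` annotated genes (propagated
#' annotation) and a non-empty complement, performs a one-sided two-sample
#' KS test of the term genes' scores against the scores of all other genes
#' in the universe, with the alternative that term-gene scores are
#' stochastically smaller (lower score = more significant, e.g. DE
#' p-values). Raw p-values are reported; a Benjamini-Hochberg column is
#' appended for convenience but DAG-induced dependence makes it heuristic.
#' Terms annotated to every gene in the universe are skipped and flagged.
#'
#' @param scores Named numeric vector over the gene universe.
#' @param annotation A [propagate_annotations()] result.
#' @param min_annotated Minimum annotated genes for a term to be tested.
#' @return An `enrichment_result` data.frame, sorted by p-value, with
#'   columns `term`, `annotated_count`, `ks_statistic`, `p_value`,
#'   `q_value_bh`; attribute `skipped` lists universe-covering terms.
#' @export
ks_enrichment <- function(scores, annotation, min_annotated = 10) {
  if (is.null(names(scores)))
    rn_validation_error("scores must be a named vector")
  universe <- names(scores)
  skipped <- character()
  rows <- list()
  for (t in names(annotation$genes_per_term)) {
    in_term <- intersect(annotation$genes_per_term[[t]], universe)
    n_t <- length(in_term)
    if (n_t < min_annotated) next
    out_term <- setdiff(universe, in_term)
    if (length(out_term) == 0) {
      skipped <- c(skipped, t)
      next
    }
    ks <- suppressWarnings(
      stats::ks.test(scores[in_term], scores[out_term],
                     alternative = "greater"))
    rows[[t]] <- data.frame(term = t, annotated_count = n_t,
                            ks_statistic = unname(ks$statistic),
                            p_value = ks$p.value,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), annotated_count = integer(),
               ks_statistic = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$q_value_bh <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' Genes behind the most significant enrichment terms
#'
#' Union of the (propagated) gene sets of the `k_terms` most significant
#' terms. Terms tied in p-value with the k-th term are all included; if
#' fewer than `k_terms` terms exist, all are used and the result is flagged.
#'
#' @param result An [ks_enrichment()] result.
#' @param annotation A [propagate_annotations()] result.
#' @param k_terms Number of top terms.
#' @return Character vector of genes; attributes `terms_used` and
#'   `truncated`.
#' @export
top_significant_genes <- function(result, annotation, k_terms = 5) {
  if (nrow(result) == 0)
    rn_validation_error("enrichment result is empty")
  truncated <- k_terms > nrow(result)
  k <- min(k_terms, nrow(result))
  cutoff <- result$p_value[k]
  use <- result$term[result$p_value <= cutoff]
  genes <- sort(unique(unlist(annotation$genes_per_term[use])))
  attr(genes, "terms_used") <- use
  attr(genes, "truncated") <- truncated
  genes
}
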