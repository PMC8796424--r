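## Config-driven orchestration of the analysis stages, with a run manifest.
## Every stage reads its inputs from files (the config or upstream stage
## outputs) and writes its results into the component directory tree, so
## running stages one-by-one equals running them all at once.

.stage_order <- c("io", "normalize", "coexpression", "enrichment",
                  "netanalysis", "regnet")

.require_upstream <- function(path, producer) {
  if (!all(file.exists(path)))
    rn_dependency_error(
      "missing upstream artifact '%s'; run stage '%s' first",
      path[!file.exists(path)][1], producer)
}

.cfg_extra <- function(config, key, required = TRUE) {
  val <- config$extra[[key]]
  if (required && (is.null(val) || !nzchar(as.character(val))))
    rn_config_error("configuration key '%s' is required for this stage", key)
  val
}

.stage_io <- function(config, tree) {
  dm <- read_design_matrix(config$design_matrix_path, config$covariates)
  dgecm <- read_dgecm(config$dgecm_path)
  comparisons <- resolve_comparisons(dm, dgecm)
  counts <- read_count_matrix(.cfg_extra(config, "counts_path"))
  missing <- setdiff(dm$sample_id, colnames(counts))
  if (length(missing) > 0)
    rn_validation_error("counts lack sample(s): %s",
                        paste(missing, collapse = ", "))
  list(outputs = character(),
       info = list(samples = nrow(dm), genes = nrow(counts),
                   comparisons = length(comparisons)))
}

.stage_normalize <- function(config, tree) {
  counts <- read_count_matrix(.cfg_extra(config, "counts_path"))
  norm <- compute_cpm(counts)
  filt <- filter_genes(counts,
                       min_cpm = as.numeric(config$extra$min_cpm %||% 1),
                       min_samples = as.integer(config$extra$min_samples %||% 2))
  factors <- tmm_factors(counts)
  lc_filtered <- compute_cpm(filt$expr)$log_cpm
  outs <- c(
    cpm = file.path(tree[["edger"]], "cpm.tsv"),
    log_cpm = file.path(tree[["edger"]], "log_cpm.tsv"),
    tmm = file.path(tree[["edger"]], "tmm_factors.tsv"),
    filtered = file.path(tree[["wgcna"]], "filtered_counts.tsv"),
    log_cpm_filtered = file.path(tree[["wgcna"]], "log_cpm_filtered.tsv"),
    removed = file.path(tree[["wgcna"]], "removed_genes.txt"))
  write_count_matrix(norm$cpm, outs[["cpm"]])
  write_count_matrix(norm$log_cpm, outs[["log_cpm"]])
  write_tsv_table(data.frame(sample_id = names(factors),
                             tmm_factor = unname(factors),
                             effective_library_size =
                               unname(colSums(counts) * factors)),
                  outs[["tmm"]])
  write_count_matrix(filt$expr, outs[["filtered"]])
  write_count_matrix(lc_filtered, outs[["log_cpm_filtered"]])
  writeLines(filt$removed, outs[["removed"]])
  list(outputs = outs,
       info = list(kept_genes = nrow(filt$expr),
                   removed_genes = length(filt$removed)))
}

.stage_coexpression <- function(config, tree) {
  input <- file.path(tree[["wgcna"]], "log_cpm_filtered.tsv")
  .require_upstream(input, "normalize")
  lc <- read_count_matrix(input)
  params <- coexpression_params(
    min_module_size = as.integer(config$extra$min_module_size %||% 30),
    merge_cut_height = as.numeric(config$extra$merge_cut_height %||% 0.25))
  net <- build_coexpression_network(lc, params)
  partition <- detect_modules(net$dissimilarity, params)
  merged <- merge_similar_modules(lc, partition,
                                  merge_cut_height = params$merge_cut_height)
  outs <- c(
    soft = file.path(tree[["wgcna"]], "soft_threshold.tsv"),
    modules = file.path(tree[["wgcna"]], "module_assignment.tsv"),
    eigengenes = file.path(tree[["wgcna"]], "eigengenes.tsv"),
    connectivity = file.path(tree[["wgcna"]], "connectivity.tsv"))
  write_tsv_table(net$fit$fit_table, outs[["soft"]])
  write_tsv_table(data.frame(gene_id = names(merged$partition$assignment),
                             module_label =
                               unname(merged$partition$assignment)),
                  outs[["modules"]])
  eg <- merged$eigengenes$eigengenes
  write_tsv_table(data.frame(sample_id = rownames(eg), eg,
                             check.names = FALSE), outs[["eigengenes"]])
  write_tsv_table(data.frame(gene_id = names(net$connectivity),
                             connectivity = unname(net$connectivity)),
                  outs[["connectivity"]])
  list(outputs = outs,
       info = list(power = net$power,
                   reached_cutoff = net$fit$reached_cutoff,
                   modules = length(setdiff(
                     unique(merged$partition$assignment), 0L))))
}

.stage_enrichment <- function(config, tree) {
  deg <- read_deg_table(.cfg_extra(config, "deg_table_path"),
                        config$extra$deg_source %||% "edger")
  dag <- load_obo(.cfg_extra(config, "obo_path"))
  ann_tab <- read_tsv_table(.cfg_extra(config, "annotation_path"))
  direct <- split(as.character(ann_tab[[2]]), as.character(ann_tab[[1]]))
  annotation <- propagate_annotations(dag, direct)
  scores <- stats::setNames(deg$p_value, sub("\\.\\d+$", "", deg$id))
  result <- ks_enrichment(scores, annotation,
                          min_annotated =
                            as.integer(config$extra$min_annotated %||% 10))
  top <- top_significant_genes(result, annotation,
                               k_terms = as.integer(config$extra$k_terms %||% 5))
  outs <- c(enrichment = file.path(tree[["network_analysis"]],
                                   "go_enrichment.tsv"),
            top_genes = file.path(tree[["network_analysis"]],
                                  "go_top_genes.txt"))
  write_tsv_table(as.data.frame(result), outs[["enrichment"]])
  writeLines(top, outs[["top_genes"]])
  list(outputs = outs,
       info = list(terms_tested = nrow(result), top_genes = length(top)))
}

.stage_netanalysis <- function(config, tree) {
  module_file <- file.path(tree[["wgcna"]], "module_assignment.tsv")
  top_file <- file.path(tree[["network_analysis"]], "go_top_genes.txt")
  .require_upstream(module_file, "coexpression")
  .require_upstream(top_file, "enrichment")
  raw <- read_edge_list(.cfg_extra(config, "reference_network_path"))
  red <- reduce_edges(raw)
  deg <- read_deg_table(.cfg_extra(config, "deg_table_path"),
                        config$extra$deg_source %||% "edger")
  alpha <- config$significance_level
  sig <- deg[!is.na(deg$q_value) & deg$q_value <= alpha, , drop = FALSE]
  sub <- overlap_deg(red$graph, sig)
  mods <- read_tsv_table(module_file)
  assignment <- stats::setNames(as.integer(mods$module_label), mods$gene_id)
  go_genes <- readLines(top_file, warn = FALSE)
  outs <- c(graph = file.path(tree[["network_analysis"]],
                              "deg_network.graphml"),
            metrics = file.path(tree[["network_analysis"]],
                                "network_metrics.tsv"),
            hubs = file.path(tree[["network_analysis"]], "hub_genes.tsv"))
  info <- list(reference_edges = red$report$kept_edges,
               deg_nodes = igraph::vcount(sub))
  if (igraph::vcount(sub) > 0) {
    sub <- encode_visual_attributes(sub)
    sub <- module_colored_graph(sub, assignment)
    write_graphml(sub, outs[["graph"]])
    metrics <- compute_metrics(sub)
    write_tsv_table(metrics$nodes, outs[["metrics"]])
    hubs <- hub_genes(sub, assignment,
                      top_k = as.integer(config$extra$hub_top_k %||% 5),
                      go_genes = go_genes)
    hub_rows <- do.call(rbind, lapply(names(hubs$per_module), function(l)
      data.frame(module = l, gene = hubs$per_module[[l]],
                 in_go_top = hubs$per_module[[l]] %in% go_genes,
                 stringsAsFactors = FALSE)))
    write_tsv_table(hub_rows %||%
                      data.frame(module = character(), gene = character(),
                                 in_go_top = logical()), outs[["hubs"]])
    info$hub_genes <- length(hubs$merged)
    info$hub_go_overlap <- length(hubs$go_intersection)
  } else {
    # empty overlap: flagged, placeholder outputs for manifest completeness
    write_graphml(sub, outs[["graph"]])
    write_tsv_table(data.frame(gene = character()), outs[["metrics"]])
    write_tsv_table(data.frame(module = character(), gene = character()),
                    outs[["hubs"]])
    info$hub_genes <- 0L
  }
  list(outputs = outs, info = info)
}

.stage_regnet <- function(config, tree) {
  module_file <- file.path(tree[["wgcna"]], "module_assignment.tsv")
  filtered_file <- file.path(tree[["wgcna"]], "log_cpm_filtered.tsv")
  .require_upstream(filtered_file, "normalize")
  lc <- read_count_matrix(filtered_file)
  tfs <- read_tf_table(.cfg_extra(config, "tf_table_path"))
  deg <- read_deg_table(.cfg_extra(config, "deg_table_path"),
                        config$extra$deg_source %||% "edger")
  sig <- sub("\\.\\d+$", "",
             deg$id[!is.na(deg$q_value) &
                    deg$q_value <= config$significance_level])
  tau <- as.numeric(config$extra$bicor_threshold %||% 0.8)
  predicted <- predicted_regulatory_network(lc, tfs, sig, tau)
  outs <- c(predicted_edges = file.path(tree[["network_analysis"]],
                                        "predicted_regnet_edges.tsv"),
            predicted_graph = file.path(tree[["network_analysis"]],
                                        "predicted_regnet.graphml"))
  write_tsv_table(predicted$edges, outs[["predicted_edges"]])
  write_graphml(regnet_to_igraph(predicted, layout = "tree"),
                outs[["predicted_graph"]])
  info <- list(predicted_edges = nrow(predicted$edges),
               tau = tau, tfs_present = length(predicted$tf_set))

  # time-series rearrangement + defaults editing for regulatory-path
  # inference, when the design has the required columns
  dm <- read_design_matrix(config$design_matrix_path)
  if (all(c("genotype", "condition", "replicate", "time") %in% names(dm))) {
    counts <- read_count_matrix(.cfg_extra(config, "counts_path"))
    ts_files <- write_drem_inputs(counts, dm, tree[["drem"]])
    outs <- c(outs, stats::setNames(ts_files,
                                    paste0("timeseries_", seq_along(ts_files))))
    template <- config$extra$drem_defaults_path
    if (!is.null(template) && file.exists(template)) {
      def_files <- vapply(seq_along(ts_files), function(i) {
        edit_drem_defaults(template, ts_files[i],
                           file.path(tree[["drem"]],
                                     sprintf("defaults_%02d.txt", i)))
      }, character(1))
      outs <- c(outs, stats::setNames(def_files,
                                      paste0("defaults_", seq_along(def_files))))
    }
    info$timeseries_files <- length(ts_files)
  }

  # merge with path-table-derived bipartite network when available
  path_dir <- config$extra$drem_path_dir
  if (!is.null(path_dir) && dir.exists(path_dir)) {
    paths <- parse_drem_tables(path_dir)
    inferred <- drem_bipartite(paths)
    combined <- merge_regulatory_networks(predicted, inferred)
    outs <- c(outs,
              drem_graph = file.path(tree[["network_analysis"]],
                                     "drem_regnet.graphml"),
              combined_edges = file.path(tree[["network_analysis"]],
                                         "combined_regnet_edges.tsv"))
    write_graphml(regnet_to_igraph(inferred, layout = "circle"),
                  outs[["drem_graph"]])
    write_tsv_table(combined$edges, outs[["combined_edges"]])
    info$drem_edges <- nrow(inferred$edges)
    info$combined_edges <- nrow(combined$edges)
  }
  list(outputs = outs, info = info)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (`io`, `normalize`,
#' `coexpression`, `enrichment`, `netanalysis`, `regnet`), each reading its
#' inputs from the configuration or from upstream stage outputs and writing
#' into the six-component directory tree. A run manifest (stages, outputs,
#' parameter snapshot, wall-clock per stage) is written to
#' `<output_dir>/manifest.json`.
#'
#' @param config_path Path to the configuration file (see [load_config()]).
#' @param stages Optional subset of stage names; default all.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config_path, stages = NULL) {
  config <- load_config(config_path)
  stages <- if (is.null(stages)) .stage_order else {
    unknown <- setdiff(stages, .stage_order)
    if (length(unknown) > 0)
      rn_validation_error("unknown stage(s): %s",
                          paste(unknown, collapse = ", "))
    .stage_order[.stage_order %in% stages]
  }
  tree <- build_directory_tree(config$output_dir)
  runners <- list(io = .stage_io, normalize = .stage_normalize,
                  coexpression = .stage_coexpression,
                  enrichment = .stage_enrichment,
                  netanalysis = .stage_netanalysis, regnet = .stage_regnet)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("rnanet")),
                   config = config_path,
                   parameters = config[setdiff(names(config), "extra")],
                   extra_parameters = config$extra,
                   stages = list())
  for (s in stages) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[%s] starting", s))
    res <- runners[[s]](config, tree)
    elapsed <- proc.time()[["elapsed"]] - t0
    missing <- res$outputs[!file.exists(res$outputs)]
    if (length(missing) > 0)
      rn_io_error("stage '%s' failed to write: %s", s,
                  paste(missing, collapse = ", "))
    manifest$stages[[s]] <- list(outputs = as.list(res$outputs),
                                 info = res$info,
                                 elapsed_seconds = round(elapsed, 3))
    message(sprintf("[%s] done in %.1fs", s, elapsed))
  }
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
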