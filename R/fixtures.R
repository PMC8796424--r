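## Deterministic synthetic-data generator for every input the pipeline
## consumes, with planted structure (modules, DEGs, enriched GO term, TF
## targets) recorded in a truth object for parameter-recovery tests.

#' Simulation specification
#'
#' Defines a time-series RNA-Seq design (timepoints x conditions x
#' genotypes x replicates) with planted co-expression modules, planted
#' differentially expressed genes, a planted enriched GO term among decoys,
#' and planted TF-target relations.
#'
#' Counts are negative binomial around log-scale means
#' `log mu = baseline + amplitude * (sqrt(rho) * latent + sqrt(1-rho) * noise)`,
#' where each module has its own latent profile over samples, so `rho` is
#' the correlation between the log-mean profiles of two genes of the same
#' module.
#'
#' @param n_genes Number of genes.
#' @param n_modules Number of planted modules (genes split evenly).
#' @param within_module_cor `rho`, log-mean within-module correlation.
#' @param n_timepoints,n_conditions,n_genotypes,n_replicates Design size;
#'   samples = product.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline `log(mean)`
#'   distribution.
#' @param amplitude Log-scale amplitude of the module signal.
#' @param n_deg Planted DEGs (shifted in non-reference condition samples);
#'   default one fifth of the genes.
#' @param deg_log2fc Planted DEG log2 fold change.
#' @param n_tfs Planted TFs (taken from the gene pool).
#' @param targets_per_tf Planted targets per TF.
#' @param tf_target_share Fraction of a target's residual (non-module)
#'   signal variance shared with its TF's driver profile; raises TF-target
#'   correlation above the within-module background.
#' @param go_terms Number of leaf GO terms (1 planted + decoys).
#' @param genes_per_term Genes annotated per term.
#' @param planted_term_effect Fraction of the planted term's genes drawn
#'   from the DEG list.
#' @param seed Integer seed; every stochastic step derives from it.
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 500, n_modules = 4,
                            within_module_cor = 0.8,
                            n_timepoints = 4, n_conditions = 2,
                            n_genotypes = 1, n_replicates = 3,
                            nb_dispersion = 0.1,
                            baseline_log_mean = log(300),
                            baseline_log_sd = 0.7,
                            amplitude = 1.5,
                            n_deg = NULL, deg_log2fc = 2,
                            n_tfs = 5, targets_per_tf = 10,
                            tf_target_share = 0.9,
                            go_terms = 21, genes_per_term = 25,
                            planted_term_effect = 0.8,
                            seed = 1) {
  spec <- as.list(environment())
  n_samples <- n_timepoints * n_conditions * n_genotypes * n_replicates
  if (is.null(n_deg)) spec$n_deg <- round(0.2 * n_genes)
  if (n_modules > 0 && n_genes %/% n_modules < 1)
    rn_validation_error("more modules than genes")
  if (within_module_cor <= 0 || within_module_cor >= 1)
    rn_validation_error("within_module_cor must lie in (0,1)")
  if (spec$n_deg + n_tfs > n_genes)
    rn_validation_error("n_deg + n_tfs exceeds n_genes")
  spec$n_samples <- n_samples
  class(spec) <- "simulation_spec"
  spec
}

.gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a count matrix with planted structure
#'
#' Generates the design matrix for the full factorial time-series layout,
#' per-module latent profiles, gene-level log-means, and negative-binomial
#' counts; planted DEG genes receive a `deg_log2fc` shift in treatment
#' (non-reference condition) samples. Deterministic for a fixed seed.
#'
#' @param spec A [simulation_spec()].
#' @return List with `expr` (counts), `dm` (design matrix data.frame),
#'   `dgecm` (comparison table) and `truth` (module labels, DEG ids, TF ->
#'   target map, latent profiles).
#' @export
simulate_counts <- function(spec = simulation_spec()) {
  set.seed(spec$seed)
  design <- expand.grid(
    replicate = seq_len(spec$n_replicates),
    time = paste0("t", seq_len(spec$n_timepoints)),
    condition = if (spec$n_conditions == 2) c("control", "stress") else
      paste0("cond", seq_len(spec$n_conditions)),
    genotype = paste0("geno", seq_len(spec$n_genotypes)),
    stringsAsFactors = FALSE)
  design <- design[, c("genotype", "condition", "time", "replicate")]
  n_s <- nrow(design)
  sample_id <- sprintf("%s_%s_%s_r%d", design$genotype, design$condition,
                       design$time, design$replicate)
  dm <- data.frame(sample_id = sample_id,
                   sample_path = file.path("reads", sample_id),
                   design, stringsAsFactors = FALSE)

  genes <- .gene_ids(spec$n_genes)
  module <- rep(seq_len(spec$n_modules), length.out = spec$n_genes)
  module <- sort(module)
  latent <- matrix(stats::rnorm(spec$n_modules * n_s), nrow = spec$n_modules)
  rho <- spec$within_module_cor
  baseline <- stats::rnorm(spec$n_genes, spec$baseline_log_mean,
                           spec$baseline_log_sd)
  noise <- matrix(stats::rnorm(spec$n_genes * n_s), nrow = spec$n_genes)

  deg <- if (spec$n_deg > 0) sample(genes, min(spec$n_deg, spec$n_genes))
         else character()

  # TF-target overlay: TF and its targets share a driver profile inside
  # their residual (non-module) signal, so their mutual correlation exceeds
  # the within-module background without disturbing module membership.
  tfs <- if (spec$n_tfs > 0) sample(setdiff(genes, deg), spec$n_tfs)
         else character()
  tf_targets <- stats::setNames(lapply(tfs, function(tf) {
    pool <- setdiff(genes[module == module[match(tf, genes)]], c(tfs, deg))
    sample(setdiff(pool, tf), min(spec$targets_per_tf, length(pool) - 1))
  }), tfs)
  phi <- spec$tf_target_share
  for (tf in tfs) {
    driver <- stats::rnorm(n_s)
    i_tf <- match(tf, genes)
    noise[i_tf, ] <- driver
    i_tg <- match(tf_targets[[tf]], genes)
    noise[i_tg, ] <- sqrt(phi) * matrix(driver, nrow = length(i_tg),
                                        ncol = n_s, byrow = TRUE) +
      sqrt(1 - phi) * noise[i_tg, , drop = FALSE]
  }
  signal <- sqrt(rho) * latent[module, , drop = FALSE] +
    sqrt(1 - rho) * noise
  log_mu <- baseline + spec$amplitude * signal
  treated <- dm$condition != dm$condition[1]
  if (length(deg) > 0 && any(treated)) {
    shift <- sample(c(-1, 1), length(deg), replace = TRUE) * spec$deg_log2fc
    log_mu[match(deg, genes), treated] <-
      log_mu[match(deg, genes), treated] + shift * log(2)
  }
  mu <- exp(log_mu)
  size <- 1 / spec$nb_dispersion
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                   nrow = spec$n_genes, dimnames = list(genes, sample_id))

  dgecm <- data.frame(
    comparison_id = "treatment_vs_reference",
    reference = paste(dm$sample_id[!treated], collapse = ";"),
    treatment = paste(dm$sample_id[treated], collapse = ";"),
    stringsAsFactors = FALSE)

  list(expr = counts, dm = dm, dgecm = dgecm,
       truth = list(module = stats::setNames(module, genes), deg = deg,
                    tfs = tfs, tf_targets = tf_targets, latent = latent,
                    baseline = baseline))
}

#' Simulate a differential-expression result table
#'
#' Emulates the upstream DE output for one comparison: planted DEGs get
#' effects near the planted log2 fold change and small p-values; the rest
#' get near-zero effects and uniform p-values. Written in the `edger`
#' dialect column convention.
#'
#' @param spec A [simulation_spec()].
#' @param truth Truth record from [simulate_counts()].
#' @return data.frame with columns `gene_id`, `logFC`, `logCPM`, `PValue`,
#'   `FDR`.
#' @export
simulate_deg_table <- function(spec, truth) {
  set.seed(spec$seed + 1L)
  genes <- names(truth$module)
  is_deg <- genes %in% truth$deg
  effect <- stats::rnorm(length(genes), 0, 0.1)
  if (any(is_deg))
    effect[is_deg] <- sample(c(-1, 1), sum(is_deg), TRUE) *
      stats::rnorm(sum(is_deg), spec$deg_log2fc, 0.2)
  p <- stats::runif(length(genes))
  if (any(is_deg)) p[is_deg] <- stats::rbeta(sum(is_deg), 0.1, 20)
  data.frame(gene_id = genes, logFC = effect,
             logCPM = truth$baseline / log(2),
             PValue = p, FDR = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Simulate a toy ontology and gene annotations
#'
#' Builds a small DAG (one root, one intermediate layer, leaf terms) and
#' annotates genes to leaves: one planted term draws `planted_term_effect`
#' of its genes from the DEG list; decoy terms sample genes uniformly.
#'
#' @param spec A [simulation_spec()].
#' @param truth Truth record from [simulate_counts()].
#' @return List with `obo_lines` (OBO 1.2 text), `annotations` (data.frame
#'   gene_id/term_id, direct), `planted_term`.
#' @export
simulate_annotations <- function(spec, truth) {
  set.seed(spec$seed + 2L)
  genes <- names(truth$module)
  n_leaf <- spec$go_terms
  n_mid <- max(2L, ceiling(n_leaf / 10))
  root <- "GO:0000001"
  mids <- sprintf("GO:%07d", 1 + seq_len(n_mid))
  leaves <- sprintf("GO:%07d", 1 + n_mid + seq_len(n_leaf))
  stanza <- function(id, name, parent = NULL) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      "namespace: biological_process",
      if (!is.null(parent)) paste0("is_a: ", parent, " ! parent"), "")
  }
  obo <- c("format-version: 1.2", "",
           stanza(root, "root"),
           unlist(lapply(seq_along(mids), function(i)
             stanza(mids[i], paste0("mid", i), root))),
           unlist(lapply(seq_along(leaves), function(i)
             stanza(leaves[i], paste0("leaf", i),
                    mids[(i - 1) %% n_mid + 1]))))
  planted <- leaves[1]
  ann <- list()
  for (i in seq_along(leaves)) {
    n_ann <- min(spec$genes_per_term, length(genes))
    members <- if (i == 1 && length(truth$deg) > 0) {
      n_from_deg <- round(spec$planted_term_effect * n_ann)
      n_from_deg <- min(n_from_deg, length(truth$deg))
      c(sample(truth$deg, n_from_deg),
        sample(setdiff(genes, truth$deg), n_ann - n_from_deg))
    } else sample(genes, n_ann)
    ann[[i]] <- data.frame(gene_id = members, term_id = leaves[i],
                           stringsAsFactors = FALSE)
  }
  list(obo_lines = obo, annotations = do.call(rbind, ann),
       planted_term = planted)
}

#' Simulate a scale-free-ish reference gene network
#'
#' Preferential-attachment random graph over the simulated gene ids
#' (heavy-tailed degree distribution), written as a 2-column edge list.
#'
#' @param spec A [simulation_spec()].
#' @param truth Truth record from [simulate_counts()].
#' @param edges_per_node Preferential-attachment edges per added node.
#' @return data.frame with `source`, `target` columns.
#' @export
simulate_reference_network <- function(spec, truth, edges_per_node = 2) {
  set.seed(spec$seed + 3L)
  genes <- names(truth$module)
  g <- igraph::sample_pa(length(genes), m = edges_per_node, directed = FALSE)
  el <- igraph::as_edgelist(g)
  perm <- sample(genes)
  data.frame(source = perm[as.integer(el[, 1])],
             target = perm[as.integer(el[, 2])],
             stringsAsFactors = FALSE)
}

#' Simulate a one-regulator recovery scenario
#'
#' Expression for a single TF, its planted targets (the TF profile plus
#' small Gaussian noise on the log scale) and independent decoy genes;
#' used to measure edge recovery of the correlation-predicted regulatory
#' network at a given threshold.
#'
#' @param n_targets Number of planted targets.
#' @param n_decoys Number of independent decoy genes.
#' @param n_samples Number of samples.
#' @param noise_sd Log-scale noise of target profiles around the TF.
#' @param seed Seed.
#' @return List with `expr` (rows: TF1, T0001..., D0001...), `tf`,
#'   `targets`, `decoys`.
#' @export
simulate_regulatory_scenario <- function(n_targets = 10, n_decoys = 50,
                                         n_samples = 24, noise_sd = 0.2,
                                         seed = 1) {
  set.seed(seed)
  driver <- stats::rnorm(n_samples, sd = 1.5)
  tf <- "TF1"
  targets <- sprintf("T%04d", seq_len(n_targets))
  decoys <- sprintf("D%04d", seq_len(n_decoys))
  expr <- rbind(
    matrix(driver, nrow = 1),
    matrix(driver, nrow = n_targets, ncol = n_samples, byrow = TRUE) +
      matrix(stats::rnorm(n_targets * n_samples, sd = noise_sd),
             nrow = n_targets),
    matrix(stats::rnorm(n_decoys * n_samples, sd = 1.5), nrow = n_decoys))
  rownames(expr) <- c(tf, targets, decoys)
  colnames(expr) <- sprintf("s%02d", seq_len(n_samples))
  list(expr = expr, tf = tf, targets = targets, decoys = decoys)
}

#' Similarity matrix with planted approximate scale-free topology
#'
#' Constructs a similarity matrix whose soft-thresholded adjacency at power
#' `beta0` has connectivities following a truncated power law (expected
#' degrees via a Chung-Lu construction), so that soft-threshold selection
#' has a known good answer.
#'
#' @param n_genes Number of genes.
#' @param gamma Power-law exponent of the expected-degree sequence.
#' @param beta0 Power at which the adjacency is scale-free.
#' @param seed Seed (the construction is deterministic from the quantile
#'   sequence; kept for interface symmetry with the other generators).
#' @return Similarity matrix (symmetric, unit diagonal, entries in `[0,1]`).
#' @export
simulate_scale_free_similarity <- function(n_genes = 300, gamma = 2.5,
                                           beta0 = 6, seed = 1) {
  set.seed(seed)
  u <- (seq_len(n_genes) - 0.5) / n_genes  # deterministic Pareto quantiles
  d <- (1 - u)^(-1 / (gamma - 1))
  d <- d / max(d) * (n_genes / 5)          # cap max expected degree
  A <- outer(d, d) / sum(d)
  A[A > 0.999] <- 0.999
  S <- A^(1 / beta0)
  diag(S) <- 1
  dimnames(S) <- list(.gene_ids(n_genes), .gene_ids(n_genes))
  S
}

#' Write a complete synthetic input bundle
#'
#' Materializes every pipeline input into `dir`: counts TSV, design matrix,
#' DGECM, DE table (edger dialect), transcript-to-gene map, per-sample
#' abundance directories, toy OBO + annotations, TF table, reference
#' network edge list, a regulator path table directory, a DREM defaults
#' template and a ready-to-run `config.yaml`.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created).
#' @return Invisible list of written paths plus the `truth` record.
#' @export
simulate_bundle <- function(spec = simulation_spec(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(spec)
  paths <- list()
  paths$counts <- file.path(dir, "counts.tsv")
  write_count_matrix(sim$expr, paths$counts)
  paths$design_matrix <- file.path(dir, "design_matrix.tsv")
  write_design_matrix(sim$dm, paths$design_matrix)
  paths$dgecm <- file.path(dir, "dgecm.tsv")
  write_tsv_table(sim$dgecm, paths$dgecm)

  deg_tab <- simulate_deg_table(spec, sim$truth)
  paths$deg_table <- file.path(dir, "deg_edger.tsv")
  write_tsv_table(deg_tab, paths$deg_table)

  genes <- rownames(sim$expr)
  t2g <- data.frame(transcript_id = paste0(genes, ".1"), gene_id = genes,
                    stringsAsFactors = FALSE)
  paths$t2g <- file.path(dir, "t2g.tsv")
  write_tsv_table(t2g, paths$t2g)

  # per-sample abundance directories for the first two samples (ingestion
  # round-trip material; kept small on purpose)
  ab_root <- file.path(dir, "abundance")
  for (s in colnames(sim$expr)[1:min(2, ncol(sim$expr))]) {
    d <- file.path(ab_root, s)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    ab <- data.frame(target_id = paste0(genes, ".1"), length = 1000,
                     eff_length = 900, est_counts = sim$expr[, s],
                     tpm = sim$expr[, s] / sum(sim$expr[, s]) * 1e6,
                     stringsAsFactors = FALSE)
    write_tsv_table(ab, file.path(d, "abundance.tsv"))
  }
  paths$abundance_root <- ab_root

  ann <- simulate_annotations(spec, sim$truth)
  paths$obo <- file.path(dir, "ontology.obo")
  writeLines(ann$obo_lines, paths$obo)
  paths$annotations <- file.path(dir, "annotations.tsv")
  write_tsv_table(ann$annotations, paths$annotations)

  tf_tab <- data.frame(tf_id = sim$truth$tfs,
                       family = rep(c("MYB", "WRKY", "bZIP", "NAC", "AP2"),
                                    length.out = length(sim$truth$tfs)),
                       stringsAsFactors = FALSE)
  paths$tf_table <- file.path(dir, "tf_table.tsv")
  write_tsv_table(tf_tab, paths$tf_table)

  refnet <- simulate_reference_network(spec, sim$truth)
  paths$reference_network <- file.path(dir, "reference_network.tsv")
  write_tsv_table(refnet, paths$reference_network)

  # regulator path tables: one path per TF over its planted targets
  path_dir <- file.path(dir, "drem_paths")
  dir.create(path_dir, showWarnings = FALSE)
  for (i in seq_along(sim$truth$tfs)) {
    tf <- sim$truth$tfs[i]
    tab <- data.frame(gene = sim$truth$tf_targets[[tf]], tf = tf,
                      score = 0.9, stringsAsFactors = FALSE)
    write_tsv_table(tab, file.path(path_dir, sprintf("path%d.tsv", i)))
  }
  paths$drem_paths <- path_dir

  paths$drem_defaults <- file.path(dir, "defaults.txt")
  writeLines(c("SAVED_MODEL_FILE\t", "Expression_Data_File\tPLACEHOLDER",
               "Gene_Annotation_Source\tUser provided"),
             paths$drem_defaults)

  cfg <- list(
    analysis_type = "timeseries",
    covariates = c("genotype", "condition", "time", "replicate"),
    dgecm_path = paths$dgecm,
    design_matrix_path = paths$design_matrix,
    significance_level = 0.05,
    read_dir = file.path(dir, "reads"),
    output_dir = file.path(dir, "output"),
    reference_path = file.path(dir, "reference.fa"),
    run_kallisto = TRUE, run_star = FALSE,
    analysis_level = "gene",
    counts_path = paths$counts,
    deg_table_path = paths$deg_table,
    deg_source = "edger",
    t2g_path = paths$t2g,
    obo_path = paths$obo,
    annotation_path = paths$annotations,
    tf_table_path = paths$tf_table,
    reference_network_path = paths$reference_network,
    drem_path_dir = path_dir,
    drem_defaults_path = paths$drem_defaults,
    bicor_threshold = 0.8,
    seed = spec$seed)
  paths$config <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, paths$config)

  invisible(c(paths, list(truth = sim$truth, spec = spec)))
}
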