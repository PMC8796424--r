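## Configuration, experimental design matrix (DM) and differential-expression
## comparison matrix (DGECM) handling, plus the analysis directory tree.

.mandatory_config_keys <- c(
  "analysis_type", "covariates", "dgecm_path", "design_matrix_path",
  "significance_level", "read_dir", "output_dir", "reference_path",
  "run_kallisto", "run_star", "analysis_level"
)

.parse_flag <- function(x) {
  if (is.logical(x)) return(isTRUE(x))
  tolower(as.character(x)) %in% c("true", "t", "yes", "1")
}

#' Load a pipeline configuration file
#'
#' Reads a configuration file in either flat `key=value` form or YAML and
#' validates it into a `pipeline_config` object. Mandatory keys are
#' `analysis_type`, `covariates`, `dgecm_path`, `design_matrix_path`,
#' `significance_level`, `read_dir`, `output_dir`, `reference_path`,
#' `run_kallisto`, `run_star` and `analysis_level`. Any other keys are kept
#' verbatim in the `extra` element so stage-specific inputs (count matrix,
#' ontology, annotation, TF table, reference network paths, thresholds, ...)
#' travel with the configuration.
#'
#' @param path Path to the configuration file.
#' @return A `pipeline_config` list with the mandatory fields plus `extra`,
#'   a named list of all unrecognised keys.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("analysis_type: timeseries", "covariates: [condition, time]",
#'   "dgecm_path: dgecm.tsv", "design_matrix_path: dm.tsv",
#'   "significance_level: 0.05", "read_dir: reads", "output_dir: out",
#'   "reference_path: genome.fa", "run_kallisto: true", "run_star: false",
#'   "analysis_level: gene"), cfg_file)
#' cfg <- load_config(cfg_file)
#' cfg$significance_level
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rn_io_error("configuration file not found: %s", path)
  txt <- readLines(path, warn = FALSE)
  looks_flat <- any(grepl("^[A-Za-z_][A-Za-z0-9_]*=", txt)) && !any(grepl(":\\s", txt))
  raw <- if (looks_flat) {
    kv <- txt[grepl("=", txt, fixed = TRUE) & !grepl("^\\s*#", txt)]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    stats::setNames(as.list(trimws(vals)), trimws(keys))
  } else {
    yaml::read_yaml(path)
  }
  present <- names(raw)[!vapply(raw, is.null, logical(1))]
  missing <- setdiff(.mandatory_config_keys, present)
  if (length(missing) > 0)
    rn_config_error("configuration missing mandatory key(s): %s",
                    paste(missing, collapse = ", "))

  covariates <- raw$covariates
  if (is.character(covariates) && length(covariates) == 1)
    covariates <- trimws(strsplit(covariates, "[,;]")[[1]])
  sig <- suppressWarnings(as.numeric(raw$significance_level))
  if (is.na(sig) || sig <= 0 || sig >= 1)
    rn_validation_error("significance_level must lie in (0,1), got '%s'",
                        as.character(raw$significance_level))
  level <- match.arg(tolower(as.character(raw$analysis_level)),
                     c("transcript", "gene", "both"))
  for (key in c("dgecm_path", "design_matrix_path", "read_dir", "output_dir",
                "reference_path")) {
    if (!nzchar(as.character(raw[[key]])))
      rn_validation_error("configuration key '%s' must be a non-empty path", key)
  }

  cfg <- list(
    analysis_type = as.character(raw$analysis_type),
    covariates = covariates,
    dgecm_path = as.character(raw$dgecm_path),
    design_matrix_path = as.character(raw$design_matrix_path),
    significance_level = sig,
    read_dir = as.character(raw$read_dir),
    output_dir = as.character(raw$output_dir),
    reference_path = as.character(raw$reference_path),
    run_kallisto = .parse_flag(raw$run_kallisto),
    run_star = .parse_flag(raw$run_star),
    analysis_level = level,
    extra = raw[setdiff(names(raw), .mandatory_config_keys)]
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Build the analysis output directory tree
#'
#' Creates the six standard component subdirectories (`drem`, `edger`,
#' `kallisto`, `network_analysis`, `sleuth`, `wgcna`) under `output_dir`.
#' Idempotent: re-running on an existing tree changes nothing.
#'
#' @param output_dir Root of the output tree; created if absent.
#' @return Named character vector mapping component name to its path.
#' @export
build_directory_tree <- function(output_dir) {
  components <- c("drem", "edger", "kallisto", "network_analysis",
                  "sleuth", "wgcna")
  ok <- dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir))
    rn_io_error("cannot create output directory: %s", output_dir)
  if (file.access(output_dir, mode = 2) != 0)
    rn_io_error("output directory is not writable: %s", output_dir)
  paths <- stats::setNames(file.path(output_dir, components), components)
  for (p in paths) {
    dir.create(p, showWarnings = FALSE)
    if (!dir.exists(p)) rn_io_error("cannot create subdirectory: %s", p)
  }
  paths
}

#' Read an experimental design matrix
#'
#' Tab-separated, header row, first column `sample_id` (unique), plus a
#' `sample_path` column and arbitrary covariate columns such as genotype,
#' condition, time and replicate.
#'
#' @param path Path to the design matrix file.
#' @param covariates Optional character vector of covariate names that must
#'   be present as columns.
#' @return A data.frame with one row per sample.
#' @export
read_design_matrix <- function(path, covariates = NULL) {
  dm <- read_tsv_table(path)
  if (names(dm)[1] != "sample_id")
    rn_parse_error("design matrix must have 'sample_id' as its first column")
  dm$sample_id <- as.character(dm$sample_id)
  if (anyDuplicated(dm$sample_id))
    rn_validation_error("duplicate sample_id in design matrix: %s",
                        paste(unique(dm$sample_id[duplicated(dm$sample_id)]),
                              collapse = ", "))
  missing_cov <- setdiff(covariates, names(dm))
  if (length(missing_cov) > 0)
    rn_validation_error("design matrix lacks covariate column(s): %s",
                        paste(missing_cov, collapse = ", "))
  dm
}

#' Write an experimental design matrix
#' @param dm Design matrix data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_design_matrix <- function(dm, path) write_tsv_table(dm, path)

#' Read a DGE comparison matrix (DGECM)
#'
#' Tab-separated with header `comparison_id`, `reference`, `treatment`; each
#' group cell holds semicolon-separated sample identifiers. One row per
#' comparison.
#'
#' @param path Path to the DGECM file.
#' @return A data.frame with character columns.
#' @export
read_dgecm <- function(path) {
  dgecm <- read_tsv_table(path, colClasses = "character")
  need <- c("comparison_id", "reference", "treatment")
  if (!all(need %in% names(dgecm)))
    rn_parse_error("DGECM must have columns: %s", paste(need, collapse = ", "))
  dgecm
}

#' Resolve DGECM rows into comparison specifications
#'
#' Each DGECM row names two sample groups; the group a sample belongs to is
#' the union (logical-or) of the semicolon-separated identifiers listed in
#' its cell. Every identifier must match a `sample_id` in the design matrix
#' and the two groups of a comparison must be disjoint and non-empty.
#'
#' @param dm Design matrix (see [read_design_matrix()]).
#' @param dgecm DGECM table (see [read_dgecm()]).
#' @return A list of `comparison_spec` objects, one per DGECM row and in row
#'   order, each with elements `comparison_id`, `reference_samples`,
#'   `treatment_samples`.
#' @export
resolve_comparisons <- function(dm, dgecm) {
  known <- dm$sample_id
  split_cell <- function(cell) {
    ids <- trimws(strsplit(as.character(cell), ";", fixed = TRUE)[[1]])
    ids[nzchar(ids)]
  }
  lapply(seq_len(nrow(dgecm)), function(i) {
    ref <- split_cell(dgecm$reference[i])
    trt <- split_cell(dgecm$treatment[i])
    for (tok in c(ref, trt)) {
      if (!tok %in% known)
        rn_validation_error(
          "DGECM row %d references unknown sample_id '%s'", i, tok)
    }
    if (length(ref) == 0 || length(trt) == 0)
      rn_validation_error("DGECM row %d has an empty sample group", i)
    both <- intersect(ref, trt)
    if (length(both) > 0)
      rn_validation_error("DGECM row %d groups overlap on: %s", i,
                          paste(both, collapse = ", "))
    structure(list(
      comparison_id = as.character(dgecm$comparison_id[i]),
      reference_samples = unique(ref),
      treatment_samples = unique(trt)
    ), class = "comparison_spec")
  })
}
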