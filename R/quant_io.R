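## Ingestion of quantification outputs (featureCounts-style count matrices,
## Kallisto-style per-sample abundance tables), transcript-to-gene
## aggregation, differential-expression result tables, and the time-series
## rearrangement consumed by regulatory-path inference (DREM-format files).

#' Read a gene-by-sample count matrix
#'
#' Tab-separated with a header of sample identifiers and gene ids in the
#' first column. Gene ids must be unique; all cells numeric.
#'
#' @param path Path to the count matrix file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_count_matrix <- function(path) {
  tab <- tryCatch(read_tsv_table(path),
                  error = function(e) rn_parse_error(conditionMessage(e)))
  if (nrow(tab) == 0 || ncol(tab) < 2)
    rn_parse_error("count matrix is empty or lacks sample columns: %s", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    rn_validation_error("duplicate gene id(s) in count matrix: %s",
                        paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) > 0)
      rn_parse_error("non-numeric cell at row %d, column '%s'",
                     bad[1], names(vals)[j])
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write a count matrix
#' @param expr Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @param id_column Header label of the gene-id column.
#' @return The path, invisibly.
#' @export
write_count_matrix <- function(expr, path, id_column = "gene_id") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write_tsv_table(df, path)
}

.validate_abundance <- function(tab, sample) {
  need <- c("target_id", "length", "eff_length", "est_counts", "tpm")
  if (!all(need %in% names(tab)))
    rn_parse_error("abundance table for '%s' lacks column(s): %s", sample,
                   paste(setdiff(need, names(tab)), collapse = ", "))
  if (anyDuplicated(tab$target_id))
    rn_validation_error("duplicate target_id in sample '%s'", sample)
  if (any(tab$est_counts < 0, na.rm = TRUE) || any(tab$tpm < 0, na.rm = TRUE))
    rn_validation_error("negative est_counts/tpm in sample '%s'", sample)
  tab
}

#' Read a directory of per-sample abundance tables
#'
#' Quantification by pseudo-alignment writes one directory per sample, named
#' after the sample identifier, each holding an `abundance.tsv` with columns
#' `target_id`, `length`, `eff_length`, `est_counts`, `tpm`.
#'
#' @param root Directory whose subdirectories are samples.
#' @param filename Abundance file name inside each sample directory.
#' @return Named list of validated abundance data.frames, one per sample.
#' @export
read_abundance_dir <- function(root, filename = "abundance.tsv") {
  if (!dir.exists(root)) rn_io_error("abundance root not found: %s", root)
  samples <- list.dirs(root, full.names = FALSE, recursive = FALSE)
  if (length(samples) == 0) rn_io_error("no sample directories under %s", root)
  out <- list()
  for (s in samples) {
    f <- file.path(root, s, filename)
    if (!file.exists(f))
      rn_io_error("sample directory '%s' has no %s", s, filename)
    out[[s]] <- .validate_abundance(read_tsv_table(f), s)
  }
  out
}

#' Read a transcript-to-gene mapping
#' @param path 2-column tab-separated file (transcript_id, gene_id).
#' @return Named character vector: `t2g[transcript_id] == gene_id`.
#' @export
read_t2g <- function(path) {
  tab <- read_tsv_table(path, colClasses = "character")
  if (ncol(tab) < 2)
    rn_parse_error("transcript-to-gene map needs 2 columns, got %d", ncol(tab))
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Aggregate transcript abundances to gene-level counts
#'
#' Sums `est_counts` over the transcripts of each gene, per sample.
#' Transcripts absent from the map are retried after stripping a trailing
#' `.<integer>` gene-model suffix (the Arabidopsis convention, e.g.
#' `AT1G01010.1` -> `AT1G01010`); transcripts still unresolved are collected
#' in a rejects report, never silently dropped.
#'
#' @param tables Named list of abundance tables (see [read_abundance_dir()]).
#' @param t2g Named vector transcript -> gene (see [read_t2g()]).
#' @return List with `expr` (gene-by-sample matrix of summed est_counts) and
#'   `rejects` (data.frame sample/target_id/est_counts of unresolved rows).
#' @export
aggregate_to_genes <- function(tables, t2g) {
  samples <- names(tables)
  rejects <- list()
  per_sample <- list()
  for (s in samples) {
    tab <- tables[[s]]
    gene <- unname(t2g[tab$target_id])
    miss <- is.na(gene)
    if (any(miss)) {
      stripped <- sub("\\.\\d+$", "", tab$target_id[miss])
      retry <- unname(t2g[stripped])
      # suffix-stripping fallback: accept the stripped id itself when it is a
      # known gene id in the map's value set
      still <- is.na(retry) & !(stripped %in% t2g)
      retry[is.na(retry) & (stripped %in% t2g)] <-
        stripped[is.na(retry) & (stripped %in% t2g)]
      gene[miss] <- retry
      bad <- which(miss)[still]
      if (length(bad) > 0)
        rejects[[s]] <- data.frame(sample = s,
                                   target_id = tab$target_id[bad],
                                   est_counts = tab$est_counts[bad],
                                   stringsAsFactors = FALSE)
    }
    keep <- !is.na(gene)
    per_sample[[s]] <- tapply(tab$est_counts[keep], gene[keep], sum)
  }
  genes <- sort(unique(unlist(lapply(per_sample, names))))
  expr <- matrix(0, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (s in samples) expr[names(per_sample[[s]]), s] <- per_sample[[s]]
  rejects <- if (length(rejects) > 0) do.call(rbind, rejects) else
    data.frame(sample = character(), target_id = character(),
               est_counts = numeric(), stringsAsFactors = FALSE)
  rownames(rejects) <- NULL
  list(expr = expr, rejects = rejects)
}

#' Rearrange counts into time-series files for regulatory-path inference
#'
#' Writes one tab-separated file per (genotype, condition, replicate) triple
#' with a `gene` column followed by one column per time point, in the time
#' order given by the design matrix. With `average_replicates = TRUE` a
#' single file per (genotype, condition) holds replicate-averaged counts.
#'
#' @param expr Gene-by-sample count matrix (columns named by sample_id).
#' @param dm Design matrix containing `genotype`, `condition`, `replicate`
#'   and `time` columns.
#' @param out_dir Output directory (created if needed).
#' @param average_replicates Average replicates instead of writing one file
#'   per replicate.
#' @return Character vector of written file paths.
#' @export
write_drem_inputs <- function(expr, dm, out_dir, average_replicates = FALSE) {
  need <- c("genotype", "condition", "replicate", "time")
  missing <- setdiff(need, names(dm))
  if (length(missing) > 0)
    rn_validation_error("design matrix lacks column(s): %s",
                        paste(missing, collapse = ", "))
  dm <- dm[dm$sample_id %in% colnames(expr), , drop = FALSE]
  time_levels <- unique(dm$time)            # time order as designed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- if (average_replicates) c("genotype", "condition") else
    c("genotype", "condition", "replicate")
  key <- interaction(dm[groups], drop = TRUE, lex.order = TRUE)
  written <- character()
  for (g in levels(key)) {
    rows <- dm[key == g, , drop = FALSE]
    cols <- lapply(time_levels, function(tp) {
      s <- rows$sample_id[rows$time == tp]
      if (length(s) == 0) {
        lbl <- paste(vapply(groups, function(cc) as.character(rows[[cc]][1]),
                            ""), collapse = ", ")
        rn_validation_error("missing time point '%s' for (%s)",
                            as.character(tp), lbl)
      }
      rowMeans(expr[, s, drop = FALSE])
    })
    out <- data.frame(gene = rownames(expr), stats::setNames(cols,
                      as.character(time_levels)), check.names = FALSE)
    stem <- paste(vapply(groups, function(cc) as.character(rows[[cc]][1]), ""),
                  collapse = "_")
    path <- file.path(out_dir, sprintf("timeseries_%s.tsv", stem))
    write_tsv_table(out, path)
    written <- c(written, path)
  }
  written
}

#' Insert a dataset path into a DREM defaults template
#'
#' Copies the `key<TAB>value` template byte-for-byte except for the
#' expression-data line, whose value is replaced with `dataset_path`.
#' Idempotent for a fixed dataset path.
#'
#' @param template_path Template defaults file.
#' @param dataset_path Path to the time-series dataset to insert.
#' @param out_path Where to write the edited file.
#' @param key Placeholder key naming the expression data file.
#' @return `out_path`, invisibly.
#' @export
edit_drem_defaults <- function(template_path, dataset_path, out_path,
                               key = "Expression_Data_File") {
  if (!file.exists(template_path))
    rn_io_error("defaults template not found: %s", template_path)
  lines <- readLines(template_path, warn = FALSE)
  hit <- grep(paste0("^", key, "\\b"), lines)
  if (length(hit) == 0)
    rn_parse_error("defaults template lacks key '%s'", key)
  lines[hit] <- paste0(key, "\t", dataset_path)
  writeLines(lines, out_path)
  invisible(out_path)
}

#' Read a differential-expression result table
#'
#' Unifies the two upstream dialects into one schema: `id`, `effect` (signed
#' beta coefficient or log-fold-change), `p_value`, `q_value`, `mean_count`.
#' The `sleuth` dialect maps `b` -> effect and `qval` -> q_value (with
#' `mean_obs` as mean count when present); the `edger` dialect maps `logFC`
#' -> effect and `FDR` -> q_value (`logCPM` as mean count when present).
#'
#' @param path Path to the table.
#' @param source Dialect, `"sleuth"` or `"edger"`.
#' @return data.frame with the unified columns plus `direction`
#'   (sign of effect).
#' @export
read_deg_table <- function(path, source = c("sleuth", "edger")) {
  source <- match.arg(source)
  tab <- read_tsv_table(path)
  dialect <- switch(source,
    sleuth = list(id = "target_id", effect = "b", p = "pval", q = "qval",
                  mean = "mean_obs"),
    edger = list(id = "gene_id", effect = "logFC", p = "PValue", q = "FDR",
                 mean = "logCPM"))
  id_col <- if (dialect$id %in% names(tab)) dialect$id else names(tab)[1]
  need <- c(dialect$effect, dialect$p, dialect$q)
  if (!all(need %in% names(tab)))
    rn_parse_error("%s-dialect table must contain columns: %s (got: %s)",
                   source, paste(need, collapse = ", "),
                   paste(names(tab), collapse = ", "))
  out <- data.frame(
    id = as.character(tab[[id_col]]),
    effect = as.numeric(tab[[dialect$effect]]),
    p_value = as.numeric(tab[[dialect$p]]),
    q_value = as.numeric(tab[[dialect$q]]),
    mean_count = if (dialect$mean %in% names(tab))
      as.numeric(tab[[dialect$mean]]) else NA_real_,
    stringsAsFactors = FALSE
  )
  bad <- with(out, p_value < 0 | p_value > 1 | q_value < 0 | q_value > 1)
  if (any(bad, na.rm = TRUE))
    rn_validation_error("p/q values outside [0,1] at row(s): %s",
                        paste(utils::head(which(bad), 5), collapse = ", "))
  out$direction <- sign(out$effect)
  out
}
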