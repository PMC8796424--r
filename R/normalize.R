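## CPM/log-CPM scaling, low-expression filtering, TMM normalization factors,
## sample clustering/PCA, and UpSet-style DEG set intersections.

#' Counts per million and log-CPM
#'
#' `cpm(g,s) = 1e6 * count(g,s) / libsize(s)`;
#' `log_cpm = log2(cpm + prior_count)`.
#'
#' @param expr Gene-by-sample count matrix.
#' @param prior_count Offset added before the log2 transform (default 0.5).
#' @return List with `cpm`, `log_cpm`, `library_sizes`.
#' @export
compute_cpm <- function(expr, prior_count = 0.5) {
  lib <- colSums(expr)
  if (any(lib <= 0))
    rn_validation_error("zero-count sample(s): %s",
                        paste(colnames(expr)[lib <= 0], collapse = ", "))
  cpm <- sweep(expr, 2, lib, "/") * 1e6
  list(cpm = cpm, log_cpm = log2(cpm + prior_count), library_sizes = lib)
}

#' Filter lowly expressed genes
#'
#' Keeps genes with CPM at least `min_cpm` in at least `min_samples` samples
#' and with a fraction of missing (NA) cells no greater than
#' `max_missing_fraction`.
#'
#' @param expr Gene-by-sample count matrix (NA allowed for imported data).
#' @param min_cpm Minimum CPM for a sample to count as expressed.
#' @param min_samples Minimum number of samples meeting `min_cpm`.
#' @param max_missing_fraction Maximum tolerated per-gene NA fraction.
#' @return List with `expr` (kept genes), `removed` (character vector) and
#'   `empty` flag (TRUE when nothing survives).
#' @export
filter_genes <- function(expr, min_cpm = 1, min_samples = 2,
                         max_missing_fraction = 0) {
  if (min_samples > ncol(expr))
    rn_validation_error("min_samples (%d) exceeds sample count (%d)",
                        min_samples, ncol(expr))
  counts <- expr
  counts[is.na(counts)] <- 0
  cpm <- compute_cpm(counts)$cpm
  n_expressed <- rowSums(cpm >= min_cpm)
  miss_frac <- rowMeans(is.na(expr))
  keep <- n_expressed >= min_samples & miss_frac <= max_missing_fraction
  if (!any(keep))
    warning("filter_genes removed every gene", call. = FALSE)
  list(expr = expr[keep, , drop = FALSE],
       removed = rownames(expr)[!keep],
       empty = !any(keep))
}

## Weighted trimmed mean of M-values between one sample and the reference.
.tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                      logratio_trim = 0.3, sum_trim = 0.05,
                      do_weighting = FALSE, a_cutoff = -1e10) {
  logR <- log2((obs / lib_obs) / (ref / lib_ref))
  absE <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / lib_obs / obs + (lib_ref - ref) / lib_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > a_cutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- if (do_weighting) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization: each sample is
#' compared against a reference sample (the one whose 75th-percentile
#' count-per-library-size is closest to the mean of those percentiles) via a
#' doubly trimmed (30% on M-values, 5% on A-values) mean of gene-wise log
#' ratios; genes with a zero count in either member of a pair are excluded.
#' Factors are rescaled so their geometric mean is 1.
#'
#' By default the trimmed mean is unweighted, which makes the factors
#' exactly invariant to multiplying any sample's counts by a positive
#' constant (depth invariance): the M-values, A-values and trim ranks are
#' functions of relative abundances only. With `do_weighting = TRUE` genes
#' are weighted by inverse asymptotic variances of the log ratios; those
#' variances depend on absolute counts, so the weighted factors are only
#' approximately depth-invariant.
#'
#' @param expr Gene-by-sample count matrix with at least two samples.
#' @param logratio_trim Two-sided trim fraction on M-values.
#' @param sum_trim Two-sided trim fraction on A-values.
#' @param do_weighting Weight gene-wise log ratios by precision.
#' @return Named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(expr, logratio_trim = 0.3, sum_trim = 0.05,
                        do_weighting = FALSE) {
  if (ncol(expr) < 2)
    rn_validation_error("TMM needs at least 2 samples, got %d", ncol(expr))
  lib <- colSums(expr)
  if (any(lib <= 0))
    rn_validation_error("zero-count sample(s): %s",
                        paste(colnames(expr)[lib <= 0], collapse = ", "))
  f75 <- apply(expr, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(expr)), function(j) {
    .tmm_pair(as.numeric(expr[, j]), as.numeric(expr[, ref]),
              lib[j], lib[ref], logratio_trim, sum_trim, do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(expr))
}

#' Effective library sizes
#' @param expr Count matrix.
#' @param factors TMM factors from [tmm_factors()].
#' @return Per-sample effective library sizes (`colSums * factor`).
#' @export
effective_library_sizes <- function(expr, factors = tmm_factors(expr)) {
  colSums(expr) * factors
}

#' Sample distance matrix and average-linkage tree
#'
#' Euclidean distances between samples on log-CPM profiles, clustered by
#' average linkage.
#'
#' @param expr Count matrix (>= 2 samples).
#' @param prior_count log-CPM prior, see [compute_cpm()].
#' @return List with `dist` (a `dist`) and `tree` (an `hclust`).
#' @export
sample_distance_tree <- function(expr, prior_count = 0.5) {
  if (ncol(expr) < 2)
    rn_validation_error("need >= 2 samples for a distance tree")
  lc <- compute_cpm(expr, prior_count)$log_cpm
  d <- stats::dist(t(lc), method = "euclidean")
  list(dist = d, tree = stats::hclust(d, method = "average"))
}

#' Principal-component coordinates of samples
#'
#' PCA of centered per-sample log-expression profiles (genes as variables).
#'
#' @param expr Count matrix.
#' @param k Number of components, at most `min(genes, samples)`.
#' @param prior_count log-CPM prior.
#' @return List with `coordinates` (samples x k), `variance_fraction`
#'   (length k, non-increasing, sums to <= 1).
#' @export
pca_coordinates <- function(expr, k = 2, prior_count = 0.5) {
  if (k > min(dim(expr)))
    rn_validation_error("k = %d exceeds min(genes, samples) = %d",
                        k, min(dim(expr)))
  lc <- compute_cpm(expr, prior_count)$log_cpm
  pc <- stats::prcomp(t(lc), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  vf <- if (tot > 0) pc$sdev[seq_len(k)]^2 / tot else rep(0, k)
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       variance_fraction = vf)
}

#' Exclusive intersection sizes of gene sets (UpSet semantics)
#'
#' For every non-empty combination of set names, counts the genes belonging
#' to exactly those sets. Counts sum to the size of the union.
#'
#' @param sets Named list of character vectors.
#' @return data.frame with `combination` (names joined by `&`), `degree`
#'   (number of sets in the combination) and `count`, sorted by decreasing
#'   count.
#' @export
deg_set_intersections <- function(sets) {
  if (length(sets) == 0 || is.null(names(sets)))
    rn_validation_error("sets must be a non-empty named list")
  universe <- unique(unlist(sets, use.names = FALSE))
  if (length(universe) == 0)
    return(data.frame(combination = character(), degree = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(sets)))
  pattern <- apply(membership, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$count, out$combination), , drop = FALSE]
}
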