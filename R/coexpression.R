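## Weighted gene co-expression network construction: correlation similarity,
## biweight midcorrelation, soft-threshold selection against approximate
## scale-free topology, adjacency, topological overlap, average-linkage
## module detection, module eigengenes and eigengene-based module merging.

#' Co-expression parameter set
#'
#' @param correlation_kind `"pearson"` (default, used for network
#'   construction) or `"bicor"` (robust biweight midcorrelation).
#' @param candidate_powers Ascending candidate soft powers.
#' @param rsq_cutoff Scale-free topology fit R^2 required of the selected
#'   power.
#' @param min_module_size Smallest cluster retained as a module.
#' @param merge_cut_height Eigengene-dissimilarity (1 - cor) below which
#'   modules merge.
#' @param tree_cut_height_quantile Quantile of dendrogram merge heights at
#'   which the gene tree is cut.
#' @param degree_bins Number of equal-width connectivity bins for the
#'   scale-free fit.
#' @return A validated `coexpression_params` list.
#' @export
coexpression_params <- function(correlation_kind = c("pearson", "bicor"),
                                candidate_powers = 1:20,
                                rsq_cutoff = 0.85,
                                min_module_size = 30,
                                merge_cut_height = 0.25,
                                tree_cut_height_quantile = 0.99,
                                degree_bins = 10) {
  correlation_kind <- match.arg(correlation_kind)
  if (rsq_cutoff <= 0 || rsq_cutoff > 1)
    rn_validation_error("rsq_cutoff must lie in (0,1]")
  if (merge_cut_height < 0 || merge_cut_height > 1)
    rn_validation_error("merge_cut_height must lie in [0,1]")
  if (is.unsorted(candidate_powers))
    rn_validation_error("candidate_powers must be ascending")
  structure(list(correlation_kind = correlation_kind,
                 candidate_powers = candidate_powers,
                 rsq_cutoff = rsq_cutoff,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 tree_cut_height_quantile = tree_cut_height_quantile,
                 degree_bins = degree_bins),
            class = "coexpression_params")
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation: observations are median-centred, scaled by nine times
#' the (unscaled) median absolute deviation, and downweighted by Tukey
#' biweights `w = (1 - u^2)^2` that vanish beyond nine MADs. Falls back to
#' Pearson correlation (with attribute `fallback = TRUE`) when either vector
#' has zero MAD, in which case the biweight standardization is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`; attribute `fallback` flags a Pearson
#'   fallback.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    rn_validation_error("bicor needs two equal-length vectors of length >= 3")
  mx <- stats::median(x); my <- stats::median(y)
  madx <- stats::median(abs(x - mx)); mady <- stats::median(abs(y - my))
  if (madx == 0 || mady == 0) {
    out <- stats::cor(x, y)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  u <- (x - mx) / (9 * madx)
  v <- (y - my) / (9 * mady)
  wx <- (1 - u^2)^2 * (abs(u) < 1)
  wy <- (1 - v^2)^2 * (abs(v) < 1)
  xt <- (x - mx) * wx
  yt <- (y - my) * wy
  out <- sum(xt * yt) / (sqrt(sum(xt^2)) * sqrt(sum(yt^2)))
  attr(out, "fallback") <- FALSE
  out
}

## All-pairs bicor between rows of a matrix (and optionally rows of y).
.bicor_matrix <- function(x, y = NULL) {
  med <- apply(x, 1, stats::median)
  mad0 <- apply(abs(x - med), 1, stats::median)
  weight_rows <- function(x, med, mad0) {
    u <- (x - med) / (9 * mad0)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    xt <- (x - med) * w
    xt / sqrt(rowSums(xt^2))
  }
  fb_x <- mad0 == 0
  xn <- x
  xn[!fb_x, ] <- weight_rows(x[!fb_x, , drop = FALSE], med[!fb_x],
                             mad0[!fb_x])
  # zero-MAD rows fall back to Pearson standardization
  if (any(fb_x)) {
    xc <- x[fb_x, , drop = FALSE] - rowMeans(x[fb_x, , drop = FALSE])
    xn[fb_x, ] <- xc / sqrt(rowSums(xc^2))
  }
  if (is.null(y)) return(tcrossprod(xn))
  medy <- apply(y, 1, stats::median)
  mady <- apply(abs(y - medy), 1, stats::median)
  fb_y <- mady == 0
  yn <- y
  yn[!fb_y, ] <- weight_rows(y[!fb_y, , drop = FALSE], medy[!fb_y],
                             mady[!fb_y])
  if (any(fb_y)) {
    yc <- y[fb_y, , drop = FALSE] - rowMeans(y[fb_y, , drop = FALSE])
    yn[fb_y, ] <- yc / sqrt(rowSums(yc^2))
  }
  tcrossprod(xn, yn)
}

#' Gene-gene similarity matrix
#'
#' `s_ij = |cor(x_i, x_j)|` over samples, Pearson by default or biweight
#' midcorrelation; unit diagonal.
#'
#' @param expr Gene-by-sample expression matrix (>= 3 samples; zero-variance
#'   genes must have been filtered out).
#' @param kind `"pearson"` or `"bicor"`.
#' @return Symmetric genes-by-genes matrix with entries in `[0, 1]`.
#' @export
similarity_matrix <- function(expr, kind = c("pearson", "bicor")) {
  kind <- match.arg(kind)
  if (ncol(expr) < 3)
    rn_validation_error("similarity needs >= 3 samples, got %d", ncol(expr))
  vars <- apply(expr, 1, stats::var)
  if (any(vars == 0))
    rn_validation_error("zero-variance gene(s): %s",
                        paste(utils::head(rownames(expr)[vars == 0], 5),
                              collapse = ", "))
  S <- if (kind == "pearson") abs(stats::cor(t(expr))) else
    abs(.bicor_matrix(expr))
  S[S > 1] <- 1
  diag(S) <- 1
  S
}

#' Soft-threshold adjacency
#'
#' Raises similarities elementwise to the soft power: `a_ij = s_ij^beta`.
#'
#' @param S Similarity matrix.
#' @param beta Soft power (>= 1).
#' @return Adjacency matrix with unit diagonal.
#' @export
adjacency_matrix <- function(S, beta) {
  if (beta < 1) rn_validation_error("soft power must be >= 1, got %g", beta)
  A <- S^beta
  diag(A) <- 1
  A
}

## Scale-free topology fit for one connectivity vector: bin connectivities
## into equal-width bins, regress log10(frequency) on log10(mean k per bin).
.scale_free_fit <- function(k, degree_bins) {
  if (max(k) - min(k) < .Machine$double.eps)
    return(list(rsq = NA_real_, slope = NA_real_))
  bins <- cut(k, breaks = degree_bins, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(keep) < 3) return(list(rsq = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  list(rsq = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Select the soft-threshold power
#'
#' For every candidate power, computes the adjacency, per-gene connectivity
#' `k_i = sum_{j != i} a_ij`, and the scale-free topology fit: genes are
#' binned into equal-width connectivity bins and `log10(frequency)` is
#' regressed on `log10(mean k)` per bin. The selected power is the smallest
#' candidate whose fit R^2 (with negative slope) reaches `rsq_cutoff`; if no
#' candidate qualifies, the candidate with maximal R^2 among negative-slope
#' fits is returned with `reached_cutoff = FALSE`.
#'
#' @param S Similarity matrix.
#' @param params A [coexpression_params()] object.
#' @return List with `power`, `reached_cutoff` and `fit_table`
#'   (power, rsq, slope, mean_k, median_k, max_k per candidate).
#' @export
pick_soft_threshold <- function(S, params = coexpression_params()) {
  n <- nrow(S)
  if (n < 20)
    warning("soft-threshold selection on fewer than 20 genes is unreliable",
            call. = FALSE)
  rows <- lapply(params$candidate_powers, function(beta) {
    A <- adjacency_matrix(S, beta)
    k <- rowSums(A) - 1
    if (max(k) - min(k) < .Machine$double.eps)
      rn_validation_error(
        "degenerate fit: all connectivities identical at power %g", beta)
    fit <- .scale_free_fit(k, params$degree_bins)
    data.frame(power = beta, rsq = fit$rsq, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$rsq) & !is.na(tab$slope) & tab$slope < 0
  qualified <- ok & tab$rsq >= params$rsq_cutoff
  if (any(qualified)) {
    power <- tab$power[which(qualified)[1]]
    reached <- TRUE
  } else {
    if (!any(ok))
      rn_validation_error("no candidate power gives a negative-slope fit")
    power <- tab$power[ok][which.max(tab$rsq[ok])]
    reached <- FALSE
  }
  list(power = power, reached_cutoff = reached, fit_table = tab)
}

#' Topological overlap matrix
#'
#' For `i != j`:
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' unit diagonal.
#'
#' @param A Symmetric adjacency with unit diagonal.
#' @return Symmetric TOM with entries in `[0, 1]` and unit diagonal.
#' @export
topological_overlap <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-8))
    rn_validation_error("adjacency must be symmetric")
  if (any(abs(diag(A) - 1) > 1e-8))
    rn_validation_error("adjacency must have unit diagonal")
  k <- rowSums(A) - 1
  L <- A %*% A - 2 * A          # removes u = i and u = j terms (diag = 1)
  kmin <- outer(k, k, pmin)
  W <- (L + A) / (kmin + 1 - A)
  diag(W) <- 1
  dimnames(W) <- dimnames(A)
  W
}

#' TOM dissimilarity
#' @param W Topological overlap matrix.
#' @return `1 - W` with zero diagonal.
#' @export
tom_dissimilarity <- function(W) {
  D <- 1 - W
  diag(D) <- 0
  D
}

#' Detect modules from TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of the dissimilarity; the tree is
#' cut at a fixed height equal to the `tree_cut_height_quantile` quantile of
#' the merge heights (a deterministic, static-height variant of branch-based
#' tree cutting). Clusters smaller than `min_module_size` are relabeled 0
#' (unassigned); surviving modules are labeled 1, 2, ... by decreasing size
#' (ties broken by first gene position).
#'
#' @param D TOM dissimilarity (genes in rows/columns, named).
#' @param params A [coexpression_params()] object.
#' @return A `module_partition` list: `assignment` (named integer vector),
#'   `sizes`, `tree` (hclust), `cut_height`.
#' @export
detect_modules <- function(D, params = coexpression_params()) {
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  cut_height <- stats::quantile(tree$height, params$tree_cut_height_quantile,
                                names = FALSE)
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  small <- as.integer(names(sizes)[sizes < params$min_module_size])
  lab <- ifelse(raw %in% small, 0L, raw)
  kept <- setdiff(unique(lab), 0L)
  if (length(kept) > 0) {
    kept_sizes <- vapply(kept, function(l) sum(lab == l), integer(1))
    first_pos <- vapply(kept, function(l) which(lab == l)[1], integer(1))
    ord <- kept[order(-kept_sizes, first_pos)]
    lab <- ifelse(lab == 0L, 0L,
                  match(lab, ord))
  }
  assignment <- stats::setNames(as.integer(lab), rownames(D))
  structure(list(assignment = assignment,
                 sizes = table(assignment[assignment != 0]),
                 tree = tree,
                 cut_height = cut_height),
            class = "module_partition")
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component, across
#' samples, of the per-gene z-scored module submatrix (unit-norm vector over
#' samples); its sign is fixed so that it correlates non-negatively with the
#' module's mean expression profile. `variance_explained` is the share of
#' total variance carried by the first component.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param partition A [detect_modules()] result (or any named assignment
#'   vector; label 0 = unassigned is skipped).
#' @return An `eigengene_set`: `eigengenes` (samples x modules matrix,
#'   columns `ME<label>`), `variance_explained` (named vector),
#'   `singleton` (labels of size-1 modules, flagged).
#' @export
module_eigengenes <- function(expr, partition) {
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  labels <- sort(setdiff(unique(assignment), 0L))
  if (length(labels) == 0)
    rn_validation_error("partition contains no modules")
  me <- matrix(NA_real_, nrow = ncol(expr), ncol = length(labels),
               dimnames = list(colnames(expr), paste0("ME", labels)))
  ve <- stats::setNames(numeric(length(labels)), paste0("ME", labels))
  singleton <- integer()
  for (idx in seq_along(labels)) {
    l <- labels[idx]
    genes <- names(assignment)[assignment == l]
    sub <- expr[genes, , drop = FALSE]
    z <- t(scale(t(sub)))            # per-gene z-score across samples
    if (length(genes) == 1) {
      e <- as.numeric(z)
      e <- e / sqrt(sum(e^2))
      me[, idx] <- e
      ve[idx] <- 1
      singleton <- c(singleton, l)
      next
    }
    sv <- svd(z)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    me[, idx] <- e
    ve[idx] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = me, variance_explained = ve,
                 singleton = singleton),
            class = "eigengene_set")
}

#' Merge modules with similar eigengenes
#'
#' Modules whose eigengenes cluster (average linkage on `1 - cor`) below
#' `merge_cut_height` are merged; eigengenes are recomputed and the process
#' iterates until no further merge occurs.
#'
#' @param expr Expression matrix.
#' @param partition Module partition.
#' @param eigengenes Matching [module_eigengenes()] result (recomputed if
#'   omitted).
#' @param merge_cut_height Dissimilarity threshold (`1 - cor`).
#' @return List with the merged `partition` and its `eigengenes`.
#' @export
merge_similar_modules <- function(expr, partition,
                                  eigengenes = module_eigengenes(expr, partition),
                                  merge_cut_height = 0.25) {
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  repeat {
    labels <- sort(setdiff(unique(assignment), 0L))
    if (length(labels) < 2 || merge_cut_height <= 0) break
    es <- module_eigengenes(expr, assignment)
    diss <- 1 - stats::cor(es$eigengenes)
    tree <- stats::hclust(stats::as.dist(diss), method = "average")
    groups <- stats::cutree(tree, h = merge_cut_height)
    if (max(groups) == length(labels)) break   # nothing merges
    new_assignment <- assignment
    for (g in unique(groups)) {
      members <- labels[groups == g]
      target <- min(members)
      new_assignment[assignment %in% members] <- target
    }
    assignment <- new_assignment
  }
  # relabel by decreasing size, 1 = largest
  labels <- setdiff(unique(assignment), 0L)
  if (length(labels) > 0) {
    sz <- vapply(labels, function(l) sum(assignment == l), integer(1))
    first_pos <- vapply(labels, function(l) which(assignment == l)[1],
                        integer(1))
    ord <- labels[order(-sz, first_pos)]
    assignment <- stats::setNames(
      ifelse(assignment == 0L, 0L, match(assignment, ord)),
      names(assignment))
  }
  partition <- structure(list(assignment = as.integer(assignment),
                              sizes = table(assignment[assignment != 0]),
                              tree = if (inherits(partition, "module_partition"))
                                partition$tree else NULL,
                              cut_height = if (inherits(partition, "module_partition"))
                                partition$cut_height else NA_real_),
                         class = "module_partition")
  names(partition$assignment) <- names(assignment)
  list(partition = partition,
       eigengenes = module_eigengenes(expr, partition))
}

#' Dendrogram-ordered TOM dissimilarity for plotting
#'
#' Reorders the dissimilarity matrix by dendrogram leaf order and attaches
#' the module label band in that order.
#'
#' @param W Topological overlap matrix.
#' @param partition A [detect_modules()] result (its tree supplies the leaf
#'   order).
#' @return List with `dissimilarity` (reordered `1 - W`), `order` (gene
#'   ids in plot order) and `module_band` (labels in plot order).
#' @export
tom_plot_data <- function(W, partition) {
  ord <- partition$tree$order
  genes <- rownames(W)[ord]
  D <- tom_dissimilarity(W)[ord, ord]
  list(dissimilarity = D, order = genes,
       module_band = partition$assignment[genes])
}

#' Build a full co-expression network
#'
#' Convenience wrapper running similarity, soft-threshold selection,
#' adjacency and TOM in sequence.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param params A [coexpression_params()] object.
#' @param beta Optional fixed soft power (skips selection).
#' @return A `coexpression_network` list: `similarity`, `adjacency`, `tom`,
#'   `dissimilarity`, `power`, `connectivity`, `fit` (selection table or
#'   NULL).
#' @export
build_coexpression_network <- function(expr, params = coexpression_params(),
                                       beta = NULL) {
  S <- similarity_matrix(expr, params$correlation_kind)
  fit <- NULL
  if (is.null(beta)) {
    fit <- pick_soft_threshold(S, params)
    beta <- fit$power
  }
  A <- adjacency_matrix(S, beta)
  W <- topological_overlap(A)
  structure(list(similarity = S, adjacency = A, tom = W,
                 dissimilarity = tom_dissimilarity(W), power = beta,
                 connectivity = rowSums(A) - 1, fit = fit),
            class = "coexpression_network")
}
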