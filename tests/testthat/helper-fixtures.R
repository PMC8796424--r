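# Shared in-code fixtures for the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# random symmetric adjacency with unit diagonal and entries in [0,1]
random_adjacency <- function(n, seed) {
  set.seed(seed)
  A <- abs(stats::cor(matrix(stats::rnorm(n * (n + 5)), n + 5, n)))
  A <- A^3
  diag(A) <- 1
  dimnames(A) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  A
}

# triple-loop evaluation of the topological overlap formula
tom_brute_force <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - 1
  W <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    l <- sum(A[i, -c(i, j)] * A[-c(i, j), j])
    W[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(W) <- dimnames(A)
  W
}

# independent all-pairs computation of degree/betweenness/closeness
brute_metrics <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    sigma[s, s] <- 1
    for (t in ord) {
      if (t == s || is.infinite(d[s, t])) next
      pred <- which(d[s, ] == d[s, t] - 1 & d[, t] == 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (is.infinite(d[s, t]) || sigma[s, t] == 0) next
      if (d[s, v] + d[v, t] == d[s, t])
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  cls <- vapply(seq_len(n), function(i) {
    dd <- d[i, -i]
    dd <- dd[is.finite(dd)]
    if (length(dd) == 0) NaN else 1 / sum(dd)
  }, numeric(1))
  list(betweenness = btw, closeness = cls, degree = igraph::degree(g))
}

# minimal valid configuration written to a temp file
write_test_config <- function(dir, overrides = list()) {
  cfg <- list(analysis_type = "timeseries",
              covariates = c("condition", "time"),
              dgecm_path = file.path(dir, "dgecm.tsv"),
              design_matrix_path = file.path(dir, "dm.tsv"),
              significance_level = 0.05,
              read_dir = file.path(dir, "reads"),
              output_dir = file.path(dir, "out"),
              reference_path = file.path(dir, "ref.fa"),
              run_kallisto = TRUE, run_star = FALSE,
              analysis_level = "gene")
  cfg[names(overrides)] <- overrides
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}

# small design matrix + DGECM pair
toy_design <- function() {
  data.frame(sample_id = c("s1", "s2", "s3", "s4"),
             sample_path = paste0("reads/s", 1:4),
             genotype = "wt",
             condition = c("control", "control", "stress", "stress"),
             time = c("t1", "t1", "t1", "t1"),
             replicate = c(1, 2, 1, 2),
             stringsAsFactors = FALSE)
}

toy_dgecm <- function() {
  data.frame(comparison_id = "c1", reference = "s1;s2",
             treatment = "s3;s4", stringsAsFactors = FALSE)
}
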