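test_that("similarity matrix equals brute-force correlation magnitudes", {
  set.seed(21)
  expr <- matrix(rnorm(10 * 6), 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  S <- similarity_matrix(expr)
  for (i in 1:10) for (j in 1:10)
    expect_equal(S[i, j], abs(cor(expr[i, ], expr[j, ])),
                 tolerance = 1e-12)
  # affine invariance and sign absorption
  expr2 <- expr
  expr2[2, ] <- 2 * expr[1, ] + 1
  expr2[3, ] <- -expr[1, ]
  S2 <- similarity_matrix(expr2)
  expect_equal(S2[1, 2], 1)
  expect_equal(S2[1, 3], 1)
  # per-gene affine rescaling leaves S unchanged
  expr3 <- expr * runif(10, 0.5, 2) + rnorm(10)
  expect_equal(similarity_matrix(expr3), S, tolerance = 1e-10)
  # zero-variance gene is an error naming the gene
  expr4 <- expr; expr4[5, ] <- 3
  expect_error(similarity_matrix(expr4), "g5",
               class = "rnanet_validation_error")
})

test_that("bicor is robust to a gross outlier and exact on affine pairs", {
  set.seed(31)
  x <- rnorm(20)
  expect_equal(unclass(bicor(x, x))[1], 1, ignore_attr = TRUE)
  expect_equal(unclass(bicor(x, -x))[1], -1, ignore_attr = TRUE)
  # one gross outlier: bicor stays closer to the uncontaminated Pearson
  y <- x + rnorm(20, sd = 0.3)
  x_c <- x; x_c[1] <- 50
  p_clean <- cor(x[-1], y[-1])
  p_dirty <- cor(x_c, y)
  b_dirty <- as.numeric(bicor(x_c, y))
  expect_lt(abs(b_dirty - p_clean), abs(p_dirty - p_clean))
  # MAD = 0 falls back to Pearson, flagged
  z <- c(rep(0, 15), 1:5)  # median deviation 0
  res <- bicor(z, rnorm(20))
  expect_true(attr(res, "fallback"))
  # matrix form agrees with the pairwise form
  m <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  Sb <- similarity_matrix(m, kind = "bicor")
  for (i in 1:5) for (j in 1:5)
    expect_equal(Sb[i, j], abs(as.numeric(bicor(m[i, ], m[j, ]))),
                 tolerance = 1e-12)
})

test_that("adjacency is elementwise powering with entries in [0,1]", {
  A <- random_adjacency(15, seed = 4)
  S <- sqrt(A)
  expect_equal(adjacency_matrix(S, 1), {
    S1 <- S; diag(S1) <- 1; S1
  })
  expect_equal(adjacency_matrix(matrix(0.5, 1, 1), 6)[1, 1], 1)  # diag reset
  A6 <- adjacency_matrix(S, 6)
  expect_equal(A6[1, 2], S[1, 2]^6)
  expect_true(all(A6 >= 0 & A6 <= 1))
  expect_error(adjacency_matrix(S, 0.5), class = "rnanet_validation_error")
})

test_that("topological overlap matches the formula on a path graph", {
  A <- diag(3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  W <- topological_overlap(A)
  expect_equal(W[1, 3], 0.5)   # (1*1 + 0)/(min(1,1) + 1 - 0)
  expect_equal(W[1, 2], 1)     # direct edge within shared neighborhood
  # two isolated nodes
  A2 <- diag(2)
  expect_equal(topological_overlap(A2)[1, 2], 0)
  # all-ones adjacency saturates at 1
  expect_true(all(topological_overlap(matrix(1, 4, 4)) == 1))
})

test_that("topological overlap equals the brute-force oracle and bounds", {
  for (seed in 1:3) {
    A <- random_adjacency(30, seed)
    W <- topological_overlap(A)
    expect_equal(W, tom_brute_force(A), tolerance = 1e-10)
    expect_true(isSymmetric(W))
    expect_true(all(W >= 0 & W <= 1 + 1e-12))
  }
})

test_that("soft threshold selection finds a scale-free fit and mean k is monotone", {
  S <- simulate_scale_free_similarity(n_genes = 300, gamma = 2.5, beta0 = 6)
  sel <- pick_soft_threshold(S)
  expect_true(sel$reached_cutoff)
  row <- sel$fit_table[sel$fit_table$power == sel$power, ]
  expect_gte(row$rsq, 0.85)
  expect_lt(row$slope, 0)
  # smallest qualifying power is chosen
  qualified <- sel$fit_table$power[!is.na(sel$fit_table$rsq) &
                                   sel$fit_table$slope < 0 &
                                   sel$fit_table$rsq >= 0.85]
  expect_equal(sel$power, min(qualified))
  # mean connectivity strictly decreasing in beta
  expect_true(all(diff(sel$fit_table$mean_k) < 0))
  # single candidate: that power comes back with its fit
  one <- pick_soft_threshold(S, coexpression_params(candidate_powers = 6))
  expect_equal(one$power, 6)
  expect_equal(nrow(one$fit_table), 1)
  # degenerate all-equal connectivities
  S_flat <- matrix(0.5, 25, 25); diag(S_flat) <- 1
  dimnames(S_flat) <- list(paste0("g", 1:25), paste0("g", 1:25))
  expect_error(suppressWarnings(pick_soft_threshold(S_flat)),
               class = "rnanet_validation_error")
})

test_that("module detection separates planted blocks and ignores order", {
  # two perfect blocks
  n <- 60
  D <- matrix(1, n, n)
  D[1:30, 1:30] <- 0
  D[31:60, 31:60] <- 0
  diag(D) <- 0
  dimnames(D) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  part <- detect_modules(D, coexpression_params(min_module_size = 10))
  expect_equal(length(unique(part$assignment)), 2)
  split1 <- unique(part$assignment[1:30])
  split2 <- unique(part$assignment[31:60])
  expect_length(split1, 1)
  expect_length(split2, 1)
  expect_false(split1 == split2)
  # labels ordered by decreasing size
  D2 <- matrix(1, 50, 50)
  D2[1:15, 1:15] <- 0; D2[16:50, 16:50] <- 0
  diag(D2) <- 0
  dimnames(D2) <- list(sprintf("g%02d", 1:50), sprintf("g%02d", 1:50))
  part2 <- detect_modules(D2, coexpression_params(min_module_size = 5))
  expect_equal(unname(unique(part2$assignment[16:50])), 1L)  # largest first
  # invariance to gene order (up to label permutation)
  perm <- sample(seq_len(n))
  part_perm <- detect_modules(D[perm, perm],
                              coexpression_params(min_module_size = 10))
  tab <- table(part$assignment[rownames(D)[perm]], part_perm$assignment)
  expect_equal(sum(tab > 0), 2)  # one-to-one label correspondence
  # clusters below min_module_size become unassigned
  part3 <- detect_modules(D2, coexpression_params(min_module_size = 20))
  expect_equal(unname(unique(part3$assignment[1:15])), 0L)
})

test_that("eigengene variance explained matches the spectral oracle", {
  set.seed(77)
  expr <- matrix(rnorm(40 * 12), 40, 12,
                 dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:12)))
  assignment <- setNames(rep(1:2, each = 20), rownames(expr))
  es <- module_eigengenes(expr, assignment)
  for (l in 1:2) {
    genes <- names(assignment)[assignment == l]
    ev <- eigen(cor(t(expr[genes, ])))$values
    expect_equal(unname(es$variance_explained[paste0("ME", l)]),
                 ev[1] / sum(ev), tolerance = 1e-8)
  }
  # unit norm and sign convention
  for (l in 1:2) {
    e <- es$eigengenes[, paste0("ME", l)]
    expect_equal(sum(e^2), 1)
    genes <- names(assignment)[assignment == l]
    z <- t(scale(t(expr[genes, ])))
    expect_gte(cor(e, colMeans(z)), 0)
  }
  # identical profiles: variance explained 1, eigengene proportional
  profile <- rnorm(12)
  same <- matrix(rep(profile, 5), 5, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  es1 <- module_eigengenes(same, setNames(rep(1, 5), rownames(same)))
  expect_equal(unname(es1$variance_explained), 1)
  expect_equal(abs(cor(es1$eigengenes[, 1], profile)), 1)
  # two orthogonal equal-variance profiles: split 50/50
  a <- rep(c(1, -1), 6); b <- rep(c(1, 1, -1, -1), 3)
  orth <- rbind(g1 = a, g2 = b)
  colnames(orth) <- paste0("s", 1:12)
  es2 <- module_eigengenes(orth, setNames(c(1, 1), c("g1", "g2")))
  expect_equal(unname(es2$variance_explained), 0.5)
  # singleton module flagged with variance 1
  es3 <- module_eigengenes(expr, setNames(c(1, 1, 2), rownames(expr)[1:3]))
  expect_equal(es3$singleton, 2L)
  expect_equal(unname(es3$variance_explained["ME2"]), 1)
})

test_that("module merging joins correlated eigengenes and only those", {
  set.seed(99)
  n_s <- 30
  e1 <- rnorm(n_s)
  e2 <- 0.95 * e1 + sqrt(1 - 0.95^2) * rnorm(n_s)  # r ~ 0.95 with e1
  e3 <- rnorm(n_s)                                 # independent
  make_module <- function(e, k, prefix) {
    m <- matrix(rep(e, k), k, byrow = TRUE) + 0.05 * rnorm(k * n_s)
    rownames(m) <- paste0(prefix, 1:k)
    m
  }
  m1 <- make_module(e1, 10, "a"); m2 <- make_module(e2, 10, "b")
  m3 <- make_module(e3, 10, "c")
  expr <- rbind(m1, m2, m3)
  colnames(expr) <- paste0("s", 1:n_s)
  assignment <- setNames(rep(1:3, each = 10), rownames(expr))
  res <- merge_similar_modules(expr, assignment, merge_cut_height = 0.25)
  merged <- res$partition$assignment
  expect_length(unique(merged), 2)
  expect_length(unique(merged[1:20]), 1)          # modules 1+2 merged
  expect_false(unique(merged[21:30]) == unique(merged[1:20]))
  # merge_cut_height = 0 leaves the partition unchanged
  res0 <- merge_similar_modules(expr, assignment, merge_cut_height = 0)
  expect_equal(length(unique(res0$partition$assignment)), 3)
  # identical eigengenes always merge
  dup <- rbind(m1, m1 + 0.01 * rnorm(length(m1)))
  rownames(dup) <- paste0("g", seq_len(nrow(dup)))
  colnames(dup) <- paste0("s", 1:n_s)
  adup <- setNames(rep(1:2, each = 10), rownames(dup))
  resd <- merge_similar_modules(dup, adup, merge_cut_height = 0.25)
  expect_length(unique(resd$partition$assignment), 1)
})

test_that("TOM plot data orders genes so module blocks are contiguous", {
  set.seed(13)
  spec <- simulation_spec(n_genes = 90, n_modules = 3, n_deg = 0,
                          n_tfs = 0, seed = 13)
  sim <- simulate_counts(spec)
  lc <- compute_cpm(sim$expr)$log_cpm
  net <- build_coexpression_network(lc, beta = 6)
  part <- detect_modules(net$dissimilarity,
                         coexpression_params(min_module_size = 10))
  pd <- tom_plot_data(net$tom, part)
  expect_setequal(pd$order, rownames(lc))
  expect_equal(rownames(pd$dissimilarity), pd$order)
  expect_true(isSymmetric(unname(pd$dissimilarity)))
  # within-module mean dissimilarity below between-module mean
  lab <- pd$module_band
  same <- outer(lab, lab, "==")
  diag(same) <- NA
  expect_lt(mean(pd$dissimilarity[same & !is.na(same)]),
            mean(pd$dissimilarity[!same & !is.na(same)]))
})
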