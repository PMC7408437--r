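test_that("bipartite normalization matches hand computations", {
  expect_equal(normalize_bipartite(matrix(1, 2, 2))$Xn, matrix(0.5, 2, 2))
  expect_equal(normalize_bipartite(matrix(c(2, 0, 0, 8), 2))$Xn, diag(2))

  set.seed(3)
  for (i in 1:10) {
    X <- matrix(runif(12 * 9, 0.1, 5), 12, 9)
    nb <- normalize_bipartite(X)
    expect_equal(svd(nb$Xn)$d[1], 1, tolerance = 1e-8)
    # oracle: explicit R^{-1/2} X C^{-1/2}
    ref <- diag(1 / sqrt(rowSums(X))) %*% X %*% diag(1 / sqrt(colSums(X)))
    expect_equal(nb$Xn, ref, tolerance = 1e-12, ignore_attr = TRUE)
  }

  bad <- matrix(c(1, 0, 2, 0), 2, byrow = TRUE,
                dimnames = list(c("a", "zero_row"), c("c1", "c2")))
  expect_error(normalize_bipartite(bad), "zero_row|c2")
  expect_error(normalize_bipartite(matrix(c(-1, 1, 1, 1), 2)), "shift")
})

test_that("noiseless block-diagonal matrices are recovered exactly by both paths", {
  # three disconnected bipartite components with unequal constants
  X <- matrix(0, 9, 12)
  X[1:3, 1:4] <- 2; X[4:6, 5:8] <- 5; X[7:9, 9:12] <- 3
  expr <- t(X)
  truth_s <- rep(1:3, each = 3); truth_g <- rep(1:3, each = 4)
  for (fit in list(spectral_cocluster(expr, k = 3, seed = 1),
                   laplacian_cocluster_oracle(expr, k = 3, seed = 1))) {
    expect_identical(adjusted_rand_index(fit$sample_labels, truth_s), 1)
    expect_identical(adjusted_rand_index(fit$gene_labels, truth_g), 1)
  }
})

test_that("the trivial singular pair is excluded and p follows ceil(log2 k)", {
  sim <- simulate_cohort(cohort_spec(n_samples = 40, n_genes = 30, seed = 2))
  m <- spectral_cocluster(sim$expr, k = 3, seed = 2)
  expect_equal(m$d[1], 1, tolerance = 1e-8)
  expect_identical(m$p, 2L)
  expect_identical(spectral_cocluster(sim$expr, k = 2, seed = 2)$p, 1L)
  expect_identical(spectral_cocluster(sim$expr, k = 8, seed = 2)$p, 3L)
  # trivial pair's Z contribution is constant: check the excluded embedding
  nb <- normalize_bipartite(t(sim$expr) - min(sim$expr))
  sv <- svd(nb$Xn, nu = 1, nv = 1)
  z1 <- c(sv$u[, 1] / sqrt(nb$r), sv$v[, 1] / sqrt(nb$c))
  expect_lt(stats::sd(z1) / abs(mean(z1)), 1e-6)
})

test_that("co-clustering is deterministic and permutation-equivariant", {
  sim <- simulate_cohort(cohort_spec(n_samples = 60, n_genes = 45, seed = 5))
  a <- spectral_cocluster(sim$expr, k = 3, seed = 17)
  b <- spectral_cocluster(sim$expr, k = 3, seed = 17)
  expect_identical(a$sample_labels, b$sample_labels)
  expect_identical(a$inertia, b$inertia)

  pr <- sample(nrow(sim$expr)); pc <- sample(ncol(sim$expr))
  perm <- spectral_cocluster(sim$expr[pr, pc], k = 3, seed = 17)
  expect_identical(
    adjusted_rand_index(perm$sample_labels[order(pc)], a$sample_labels), 1)
  expect_identical(
    adjusted_rand_index(perm$gene_labels[order(pr)], a$gene_labels), 1)

  # sum of singular values invariant under permutation
  shifted <- t(sim$expr) - min(sim$expr)
  d0 <- sum(svd(normalize_bipartite(shifted)$Xn)$d)
  d1 <- sum(svd(normalize_bipartite(shifted[pc, pr])$Xn)$d)
  expect_equal(d0, d1, tolerance = 1e-8)
})

test_that("planted checkerboards are recovered at the stated noise level", {
  ok <- vapply(1:5, function(s) {
    sim <- simulate_cohort(cohort_spec(n_samples = 90, n_genes = 60, seed = s))
    m <- spectral_cocluster(sim$expr, k = 3, seed = s)
    adjusted_rand_index(m$sample_labels, sim$truth$sample_labels)
  }, numeric(1))
  expect_true(all(ok >= 0.95))
})

test_that("dual solution paths agree on small well-separated instances", {
  set.seed(11)
  agree <- vapply(1:20, function(i) {
    pb <- planted_block_matrix()
    a <- spectral_cocluster(pb$expr, k = 2, seed = i)
    b <- laplacian_cocluster_oracle(pb$expr, k = 2, seed = i)
    adjusted_rand_index(a$sample_labels, b$sample_labels) == 1
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("k = 2 reduces to a Fiedler-like sign split", {
  set.seed(13)
  pb <- planted_block_matrix(m = 24, n = 16, sep = 3)
  fit <- laplacian_cocluster_oracle(pb$expr, k = 2, seed = 1)
  z <- fit$Z[seq_len(24), 1]
  sign_split <- as.integer(z > 0) + 1L
  expect_identical(adjusted_rand_index(sign_split, fit$sample_labels), 1)
  expect_identical(adjusted_rand_index(sign_split, pb$rows), 1)
})

test_that("reorder_checkerboard permutes without touching values", {
  sim <- simulate_cohort(cohort_spec(n_samples = 30, n_genes = 20, seed = 4))
  m <- spectral_cocluster(sim$expr, k = 3, seed = 4)
  ro <- reorder_checkerboard(sim$expr, m)
  # round trip restores the matrix
  inv_r <- order(ro$gene_order); inv_c <- order(ro$sample_order)
  expect_identical(ro$expr[inv_r, inv_c], sim$expr)
  # labels contiguous after reordering
  expect_true(!is.unsorted(m$gene_labels[ro$gene_order]))
  expect_true(!is.unsorted(m$sample_labels[ro$sample_order]))
  # identity when already contiguous (planted labels are sorted)
  ident <- reorder_checkerboard(sim$expr, list(sample_labels = sim$truth$sample_labels,
                                               gene_labels = sim$truth$gene_labels))
  expect_identical(ident$sample_order, seq_len(ncol(sim$expr)))
  expect_identical(ident$gene_order, seq_len(nrow(sim$expr)))
  # variance decomposition: within-block variance below between-block variance
  blocks <- split(as.vector(sim$expr),
                  list(sim$truth$gene_labels[row(sim$expr)],
                       sim$truth$sample_labels[col(sim$expr)]))
  within <- mean(vapply(blocks, stats::var, numeric(1)))
  between <- stats::var(vapply(blocks, mean, numeric(1)))
  expect_lt(within, between)

  expect_error(reorder_checkerboard(sim$expr[1:5, ], m), "dimensions")
})

test_that("guard rails: k bounds and oracle size refusal", {
  sim <- simulate_cohort(cohort_spec(n_samples = 10, n_genes = 8, seed = 1))
  expect_error(spectral_cocluster(sim$expr, k = 9, seed = 1), "k exceeds")
  expect_error(spectral_cocluster(sim$expr, k = 1, seed = 1), "k")
  big <- simulate_cohort(cohort_spec(n_samples = 300, n_genes = 200, seed = 1))
  expect_error(laplacian_cocluster_oracle(big$expr, k = 2, seed = 1), "refuses")
})
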