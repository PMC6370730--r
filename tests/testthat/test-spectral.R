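block_diag_kernel <- function(sizes) {
  n <- sum(sizes)
  m <- matrix(0, n, n)
  at <- 0
  for (s in sizes) {
    m[at + seq_len(s), at + seq_len(s)] <- 1
    at <- at + s
  }
  dimnames(m) <- list(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
  similarity_kernel(m, kind = "fused")
}

test_that("the normalized Laplacian has the expected spectrum", {
  id <- diag(4); dimnames(id) <- list(paste0("P", 1:4), paste0("P", 1:4))
  expect_equal(normalized_laplacian(id), matrix(0, 4, 4), ignore_attr = TRUE)

  # two disconnected blocks: eigenvalue 0 with multiplicity 2
  L2 <- normalized_laplacian(block_diag_kernel(c(3, 4)))
  ev <- eigen(L2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(abs(ev))[1:2], c(0, 0), tolerance = 1e-12)
  expect_gt(sort(ev)[3], 0.1)

  # eigenvalues of any valid affinity lie in [0, 2]
  withr::with_seed(21, {
    for (rep in 1:5) {
      m <- matrix(runif(64), 8, 8); m <- (m + t(m)) / 2; diag(m) <- 1
      dimnames(m) <- list(paste0("P", 1:8), paste0("P", 1:8))
      ev <- eigen(normalized_laplacian(m), symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-10)
      expect_lte(max(ev), 2 + 1e-10)
    }
  })

  zero_row <- rbind(c(1, 0, 0), c(0, 1, 1), c(0, 1, 1)) * 1.0
  zero_row[1, 1] <- 0
  dimnames(zero_row) <- list(c("Pa", "Pb", "Pc"), c("Pa", "Pb", "Pc"))
  expect_error(normalized_laplacian(zero_row), "zero total similarity.*Pa")
})

test_that("spectral embedding is orthonormal and attains the eigenvalue-sum trace", {
  withr::with_seed(22, {
    m <- matrix(runif(100, 0.05, 1), 10, 10); m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(sprintf("P%02d", 1:10), sprintf("P%02d", 1:10))
  })
  L <- normalized_laplacian(m)
  for (C in c(2, 5, 9)) { # includes C = n - 1
    emb <- spectral_embed(L, C)
    Q <- emb$vectors
    expect_equal(crossprod(Q), diag(C), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sum(diag(t(Q) %*% L %*% Q)), sum(emb$eigenvalues), tolerance = 1e-8)
    # sign convention: largest-magnitude entry of each eigenvector is positive
    for (j in seq_len(C)) expect_gt(Q[which.max(abs(Q[, j])), j], 0)
    # row-normalized coordinates have unit length
    expect_equal(unname(rowSums(emb$rows^2)), rep(1, 10), tolerance = 1e-10)
  }
  expect_error(spectral_embed(L, 1), "2 <= C")
  expect_error(spectral_embed(L, 10), "C <= n - 1")

  # two disconnected blocks: embedding rows collapse to 2 distinct points
  Lb <- normalized_laplacian(block_diag_kernel(c(4, 4)))
  rows <- spectral_embed(Lb, 2)$rows
  expect_equal(max(dist(rows[1:4, ])), 0, tolerance = 1e-8)
  expect_equal(max(dist(rows[5:8, ])), 0, tolerance = 1e-8)
  dm <- as.matrix(dist(rows))
  expect_gt(min(dm[1:4, 5:8]), 0.5) # the two blocks sit far apart
})

test_that("k-means on the embedding matches exhaustive 2-partition search", {
  withr::with_seed(23, {
    X <- rbind(matrix(rnorm(8, mean = 0, sd = 0.3), 4, 2),
               matrix(rnorm(4, mean = 4, sd = 0.3), 2, 2))
  })
  rownames(X) <- paste0("P", 1:6)
  asg <- cluster_embedding(X, C = 2, seed = 5)
  expect_equal(wss_of(X, asg$cluster), min_wss_bruteforce(X), tolerance = 1e-10)

  # determinism: same seed, same labels
  expect_identical(asg$cluster, cluster_embedding(X, C = 2, seed = 5)$cluster)
  # relabelling is by descending cluster size
  expect_equal(asg$cluster[1:4], rep(1L, 4))
})

test_that("spectral clustering attains the brute-force minimum normalized cut", {
  for (s in 1:10) {
    sizes <- if (s %% 2 == 0) c(3, 4) else c(2, 5)
    K <- two_block_kernel(sizes[1], sizes[2], seed = s)
    asg <- spectral_cluster(K, C = 2, seed = s)
    expect_lte(ncut_value(K, asg$cluster),
               min_ncut_bruteforce(K) * (1 + 1e-6))
  }

  # perfect blocks are recovered exactly
  Kp <- block_diag_kernel(c(4, 4))
  asg <- spectral_cluster(Kp, C = 2, seed = 1)
  expect_equal(ari(asg$cluster, rep(1:2, each = 4)), 1)
  expect_error(spectral_cluster(Kp, C = 1, seed = 1), "2 <= C")
})

test_that("scan_clusters returns one scored row per candidate C", {
  sim <- simulate_cohort(synthetic_spec(n_patients = 30, n_clusters = 2,
                                        n_features = c(25, 20)), seed = 31)
  fit <- skf(sim$cohort)
  sc <- scan_clusters(fit$fused, sim$cohort$survival, C_range = 2:6, seed = 1)
  expect_s3_class(sc, "cluster_scan")
  expect_equal(nrow(sc), 5L)
  expect_equal(sc$C, 2:6)
  expect_equal(sc$neg_log10_p, -log10(sc$p_value))
  expect_true(all(sc$df == sc$C - 1L))
})
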