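col_stochastic <- function(m, ids = paste0("P", seq_len(nrow(m)))) {
  dimnames(m) <- list(ids, ids)
  similarity_kernel(sweep(m, 2, colSums(m), "/"), kind = "normalized")
}

identity_sparse <- function(n, ids = paste0("P", seq_len(n))) {
  m <- diag(n); dimnames(m) <- list(ids, ids)
  similarity_kernel(m, kind = "sparse")
}

test_that("alpha = 0 reaches the anchored fixed point after one iteration", {
  withr::with_seed(2, {
    P <- lapply(1:3, function(i) col_stochastic(matrix(runif(16, 0.1, 1), 4, 4)))
    S <- lapply(1:3, function(i) {
      K <- matrix(runif(16, 0.1, 1), 4, 4)
      K <- (K + t(K)) / 2
      dimnames(K) <- list(paste0("P", 1:4), paste0("P", 1:4))
      sparsify_kernel(K, knn_sets(K, 2))
    })
  })
  res <- skf_iterate(P, S, alpha = 0, max_iters = 10)
  expect_true(res$converged)
  expect_lte(res$iterations_run, 2L)
  expect_equal(res$history[2], 0) # the state after iteration 1 never moves again
  # fixed point is the column-renormalized mean of the other views' initial P
  for (l in 1:3) {
    expected <- Reduce(`+`, lapply(P[-l], as.matrix)) / 2
    expected <- sweep(expected, 2, colSums(expected), "/")
    expect_equal(as.matrix(res$P_list[[l]]), expected, tolerance = 1e-12)
  }
})

test_that("alpha = 1 with identity diffusion kernels swaps two views (period 2)", {
  withr::with_seed(3, {
    A <- col_stochastic(matrix(runif(9, 0.1, 1), 3, 3))
    B <- col_stochastic(matrix(runif(9, 0.1, 1), 3, 3))
  })
  S <- list(identity_sparse(3), identity_sparse(3))
  one <- skf_iterate(list(A, B), S, alpha = 1, max_iters = 1)
  expect_equal(as.matrix(one$P_list[[1]]), as.matrix(B))
  expect_equal(as.matrix(one$P_list[[2]]), as.matrix(A))
  expect_false(one$converged)
  two <- skf_iterate(list(A, B), S, alpha = 1, max_iters = 2)
  expect_equal(as.matrix(two$P_list[[1]]), as.matrix(A))
  expect_equal(as.matrix(two$P_list[[2]]), as.matrix(B))
})

test_that("identical views are a fixed point at alpha = 0", {
  withr::with_seed(4, P0 <- col_stochastic(matrix(runif(25, 0.1, 1), 5, 5)))
  S0 <- identity_sparse(5)
  res <- skf_iterate(list(P0, P0, P0), list(S0, S0, S0), alpha = 0, max_iters = 5)
  expect_equal(as.matrix(res$P_list[[1]]), as.matrix(P0), tolerance = 1e-12)
  expect_true(res$converged)
})

test_that("kernel combination is the elementwise mean", {
  a <- diag(2); b <- rbind(c(0, 1), c(1, 0))
  dimnames(a) <- dimnames(b) <- list(c("Pa", "Pb"), c("Pa", "Pb"))
  expect_equal(as.matrix(combine_kernels(list(a, b))),
               matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(as.matrix(combine_kernels(list(a, a))), a)
  # linearity: combine(c * P) = c * combine(P)
  withr::with_seed(8, m <- list(matrix(runif(9), 3, 3), matrix(runif(9), 3, 3)))
  m <- lapply(m, function(x) { dimnames(x) <- list(paste0("P", 1:3), paste0("P", 1:3)); x })
  expect_equal(as.matrix(combine_kernels(lapply(m, function(x) 3 * x))),
               3 * as.matrix(combine_kernels(m)))
})

test_that("mutual-neighbour weights score reciprocity case by case", {
  # N_1 = {1,2}, N_2 = {2,3}, N_3 = {3,2}: 1->2 one-way, 2<->3 mutual, 1,3 none
  nb <- manual_knn_sets(list(c(1L, 2L), c(2L, 3L), c(3L, 2L)), ids = paste0("P", 1:3))
  w <- mutual_knn_weights(nb)
  expect_equal(w[1, 2], 0.5)
  expect_equal(w[2, 3], 1)
  expect_equal(w[1, 3], 0)
  expect_equal(unname(diag(w)), rep(1, 3))
  expect_equal(w, t(w))

  # saturation: everyone neighbours everyone -> all-ones mask
  full <- manual_knn_sets(rep(list(1:4), 4), ids = paste0("P", 1:4))
  expect_equal(mutual_knn_weights(full), matrix(1, 4, 4), ignore_attr = TRUE)
})

test_that("the mask multiplies elementwise then symmetrizes, exactly", {
  K <- rbind(c(1, 0.8), c(0.6, 1))
  w <- rbind(c(1, 0.5), c(0.5, 1))
  dimnames(K) <- list(c("Pa", "Pb"), c("Pa", "Pb"))
  out <- as.matrix(apply_weights(K, w))
  expect_equal(out, rbind(c(1, 0.35), c(0.35, 1)), ignore_attr = TRUE)

  withr::with_seed(9, {
    Kr <- matrix(runif(36), 6, 6)
    dimnames(Kr) <- list(paste0("P", 1:6), paste0("P", 1:6))
    nb <- knn_sets((Kr + t(Kr)) / 2, 2)
  })
  wr <- mutual_knn_weights(nb)
  Ks <- as.matrix(apply_weights(Kr, wr))
  sym <- (Kr + t(Kr)) / 2
  expect_equal(Ks[wr == 0], rep(0, sum(wr == 0)))     # masked entries vanish
  expect_equal(Ks[wr == 1], sym[wr == 1])             # mutual entries untouched
})

test_that("fusing three copies of one view at alpha = 0 masks the single-view P", {
  view <- withr::with_seed(6, make_view(matrix(rnorm(80), 10, 8), name = "v"))
  coh <- cohort(list(view, view, view))
  fit <- skf(coh, alpha = 0, k = 3)

  # independent composition from the module operations
  z <- zscore_normalize(view)
  D <- pairwise_distance_kernel(z)
  Ksim <- distance_to_similarity(D, k = 3)
  P <- as.matrix(normalize_kernel(Ksim))
  w <- mutual_knn_weights(knn_sets(P, 3))
  expected <- (w * P + t(w * P)) / 2
  expect_equal(as.matrix(fit$fused), expected, tolerance = 1e-10)
})

test_that("the fused kernel is permutation-equivariant, symmetric, and masked", {
  coh <- random_cohort(n = 12, n_views = 3, m = 10, seed = 10)
  fit <- skf(coh, alpha = 0.5, k = 4)
  Kf <- as.matrix(fit$fused)
  expect_equal(Kf, t(Kf))
  expect_true(all(is.finite(Kf)) && all(Kf >= 0))

  withr::with_seed(1, perm <- sample(12))
  views_p <- lapply(coh$views, function(v) {
    expression_view(v$values[perm, , drop = FALSE], view_name = v$view_name)
  })
  fit_p <- skf(cohort(views_p), alpha = 0.5, k = 4)
  expect_equal(as.matrix(fit_p$fused), Kf[perm, perm], tolerance = 1e-10)
})

test_that("fused similarity is higher within planted clusters than between", {
  sim <- simulate_cohort(synthetic_spec(n_patients = 40, n_clusters = 2,
                                        n_features = c(30, 25, 20)), seed = 12)
  fit <- skf(sim$cohort)
  Kf <- as.matrix(fit$fused)
  lab <- sim$labels$true_cluster
  same <- outer(lab, lab, "==") & upper.tri(Kf)
  diff <- outer(lab, lab, "!=") & upper.tri(Kf)
  expect_gt(mean(Kf[same]), mean(Kf[diff]))
})
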