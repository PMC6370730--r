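test_that("pairwise squared distances match hand computation and are metric", {
  v <- make_view(rbind(c(0, 0), c(3, 4), c(6, 8)))
  D <- pairwise_distance_kernel(v)
  expect_equal(D$kind, "distance")
  m <- as.matrix(D)
  expect_equal(m[1, 2], 25) # 9 + 16
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(m, t(m))

  # duplicated feature vectors give zero off-diagonal distance
  vd <- make_view(rbind(c(1, 2), c(1, 2), c(5, 5)))
  expect_equal(as.matrix(pairwise_distance_kernel(vd))[1, 2], 0)

  # triangle inequality on sqrt(D) for random inputs
  withr::with_seed(7, {
    for (rep in 1:5) {
      d <- sqrt(as.matrix(pairwise_distance_kernel(make_view(matrix(rnorm(40), 8, 5)))))
      for (i in 1:8) for (j in 1:8) for (k in 1:8) {
        expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
      }
    }
  })
})

test_that("scaled exponential conversion matches a term-by-term scalar oracle", {
  # three patients on a line at 0, 1, 10; one feature; k = 1, mu = 0.5
  v <- make_view(matrix(c(0, 1, 10), 3, 1))
  D <- pairwise_distance_kernel(v)
  expect_equal(as.matrix(D), rbind(c(0, 1, 100), c(1, 0, 81), c(100, 81, 0)),
               ignore_attr = TRUE)
  K <- as.matrix(distance_to_similarity(D, k = 1, mu = 0.5))

  # scalar oracle: nearest neighbour of 1 is 2 (D=1), of 2 is 1 (D=1),
  # of 3 is 2 (D=81); mean local squared distances:
  m1 <- 1; m2 <- 1; m3 <- 81
  eps12 <- (m1 + m2 + 1) / 3
  eps13 <- (m1 + m3 + 100) / 3
  eps23 <- (m2 + m3 + 81) / 3
  expect_equal(K[1, 2], exp(-1 / (0.5 * eps12)))
  expect_equal(K[1, 3], exp(-100 / (0.5 * eps13)))
  expect_equal(K[2, 3], exp(-81 / (0.5 * eps23)))
  expect_equal(unname(diag(K)), rep(1, 3))
  expect_true(all(K > 0 & K <= 1))

  # identical patients: all-zero distances floor the local scale, K is all-ones
  v0 <- make_view(matrix(0, 3, 2))
  D0 <- pairwise_distance_kernel(v0)
  expect_message(K0 <- distance_to_similarity(D0, k = 1), "zero local scale")
  expect_equal(as.matrix(K0), matrix(1, 3, 3), ignore_attr = TRUE)

  # closer neighbours stay more similar (rank preservation within a row)
  vg <- make_view(matrix(c(0, 1, 2), 3, 1))
  Kg <- as.matrix(distance_to_similarity(pairwise_distance_kernel(vg), k = 2))
  expect_gt(Kg[1, 2], Kg[1, 3])
})

test_that("knn sets include self, break ties by index, and match argsort", {
  # all off-diagonal similarities equal: ties resolved to smallest indices
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  dimnames(m) <- list(paste0("P", 1:4), paste0("P", 1:4))
  nb <- knn_sets(similarity_kernel(m), k = 2)
  expect_equal(sort(nb$sets[[1]]), c(1L, 2L, 3L))
  expect_equal(sort(nb$sets[[4]]), c(1L, 2L, 4L))

  # unique similarities: sets match an independent argsort
  withr::with_seed(11, {
    r <- matrix(runif(64), 8, 8)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    dimnames(r) <- list(paste0("P", 1:8), paste0("P", 1:8))
  })
  nb2 <- knn_sets(similarity_kernel(r), k = 3)
  for (i in 1:8) {
    expected <- setdiff(order(r[i, ], decreasing = TRUE), i)[1:3]
    expect_setequal(nb2$sets[[i]], c(i, expected))
    expect_length(nb2$sets[[i]], 4L) # k + 1, self included
    expect_true(i %in% nb2$sets[[i]])
  }

  # saturation: k = n - 1 includes everyone
  nb3 <- knn_sets(similarity_kernel(r), k = 7)
  for (i in 1:8) expect_setequal(nb3$sets[[i]], 1:8)

  expect_error(knn_sets(similarity_kernel(r), k = 8), "k <= n - 1")
})

test_that("column normalization matches hand examples and flags zero columns", {
  id3 <- diag(3); dimnames(id3) <- list(paste0("P", 1:3), paste0("P", 1:3))
  expect_equal(as.matrix(normalize_kernel(id3)), id3)

  ones <- matrix(1, 4, 4); dimnames(ones) <- list(paste0("P", 1:4), paste0("P", 1:4))
  expect_equal(as.matrix(normalize_kernel(ones)),
               matrix(0.25, 4, 4), ignore_attr = TRUE)

  m <- rbind(c(1, 2), c(3, 4))
  dimnames(m) <- list(c("Pa", "Pb"), c("Pa", "Pb"))
  expect_equal(as.matrix(normalize_kernel(m)),
               rbind(c(0.25, 1 / 3), c(0.75, 2 / 3)), ignore_attr = TRUE)

  z <- rbind(c(1, 0), c(2, 0))
  dimnames(z) <- list(c("Pa", "Pb"), c("Pa", "Pb"))
  expect_error(normalize_kernel(z), "zero column sum.*Pb")
})

test_that("sparsification restricts rows to neighbourhoods and row-normalizes", {
  m <- rbind(c(2, 1, 3), c(1, 2, 1), c(3, 1, 2))
  dimnames(m) <- list(paste0("P", 1:3), paste0("P", 1:3))
  nb <- manual_knn_sets(list(c(1L, 3L), c(2L, 1L), c(3L, 1L)), ids = paste0("P", 1:3))
  S <- as.matrix(sparsify_kernel(m, nb))
  expect_equal(S[1, ], c(0.4, 0, 0.6), ignore_attr = TRUE) # 2/(2+3), 0, 3/(2+3)

  # saturated neighbourhoods reduce to plain row normalization
  nb_all <- manual_knn_sets(rep(list(1:3), 3), ids = paste0("P", 1:3))
  expect_equal(as.matrix(sparsify_kernel(m, nb_all)),
               sweep(m, 1, rowSums(m), "/"))

  # self-only neighbourhoods on the identity give the identity
  id3 <- diag(3); dimnames(id3) <- list(paste0("P", 1:3), paste0("P", 1:3))
  nb_self <- manual_knn_sets(list(1L, 2L, 3L), ids = paste0("P", 1:3))
  expect_equal(as.matrix(sparsify_kernel(id3, nb_self)), id3)

  # rows sum to 1 with exactly |N_i| nonzeros, for random kernels
  withr::with_seed(5, {
    r <- matrix(runif(100, 0.01, 1), 10, 10)
    r <- (r + t(r)) / 2; diag(r) <- 1
    dimnames(r) <- list(sprintf("P%02d", 1:10), sprintf("P%02d", 1:10))
    K <- similarity_kernel(r)
    nbk <- knn_sets(K, k = 3)
    Sk <- as.matrix(sparsify_kernel(K, nbk))
    expect_equal(unname(rowSums(Sk)), rep(1, 10), tolerance = 1e-12)
    expect_equal(unname(rowSums(Sk > 0)), rep(4, 10))
  })
})
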