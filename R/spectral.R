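#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^{-1/2} K D^{-1/2}` where `D` is the diagonal degree matrix of
#' the (symmetric, nonnegative) affinity `K`. `L` is positive semidefinite
#' with eigenvalues in `[0, 2]`; its low eigenvectors carry the cluster
#' structure of the affinity graph (the relaxation of the normalized cut).
#'
#' @param K A `similarity_kernel` (kind `"fused"` or `"similarity"`) or a
#'   symmetric nonnegative matrix. Every patient must have positive degree.
#' @return A symmetric n-by-n matrix.
#' @export
normalized_laplacian <- function(K) {
  m <- as_kernel_matrix(K)
  if (max(abs(m - t(m))) > 1e-10) stopf("affinity must be symmetric")
  deg <- rowSums(m)
  if (any(deg <= 0)) {
    bad <- rownames(m)[deg <= 0] %||% which(deg <= 0)
    stopf("zero total similarity for patient(s): %s", toString(head(bad, 5)))
  }
  inv_sqrt <- 1 / sqrt(deg)
  L <- -m * outer(inv_sqrt, inv_sqrt)
  diag(L) <- diag(L) + 1
  (L + t(L)) / 2
}

#' Spectral embedding from a normalized Laplacian
#'
#' Takes the eigenvectors of the `C` smallest eigenvalues of `L` (the
#' relaxed minimizer of the normalized-cut trace problem), fixes each
#' eigenvector's sign so its largest-magnitude entry is positive, and also
#' returns the row-normalized coordinates used for k-means (the
#' Ng-Jordan-Weiss recipe). Rows with zero norm are left at zero.
#'
#' @param L_plus Symmetric normalized Laplacian matrix.
#' @param C Number of clusters / embedding dimensions, `2 <= C <= n - 1`.
#' @return An object of class `spectral_embedding` with `vectors` (n-by-C,
#'   orthonormal, sign-fixed), `rows` (n-by-C, unit-length rows), and
#'   `eigenvalues` (the C smallest, ascending).
#' @export
spectral_embed <- function(L_plus, C) {
  n <- nrow(L_plus)
  C <- as.integer(C)
  if (C < 2L || C > n - 1L) stopf("`C` must satisfy 2 <= C <= n - 1 (n = %d, C = %d)", n, C)
  e <- eigen(L_plus, symmetric = TRUE) # eigenvalues descending
  vals <- e$values[seq(n, n - C + 1L)] # ascending smallest C
  Q <- e$vectors[, seq(n, n - C + 1L), drop = FALSE]
  for (j in seq_len(C)) {
    peak <- which.max(abs(Q[, j]))
    if (Q[peak, j] < 0) Q[, j] <- -Q[, j]
  }
  norms <- sqrt(rowSums(Q^2))
  zero <- norms < 1e-12
  if (any(zero)) {
    inform(sprintf("spectral_embed: %d zero row(s) left unnormalized", sum(zero)))
    norms[zero] <- 1
  }
  rows <- Q / norms
  rownames(Q) <- rownames(rows) <- rownames(L_plus)
  structure(list(vectors = Q, rows = rows, eigenvalues = vals),
            class = "spectral_embedding")
}

#' @export
print.spectral_embedding <- function(x, ...) {
  cat(sprintf("<spectral_embedding> %d patients x %d dimensions\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Cluster a spectral embedding with seeded k-means
#'
#' Runs k-means (25 restarts, best within-cluster sum of squares kept) on
#' the row-normalized spectral coordinates under a fixed seed, then relabels
#' clusters by descending size so labels are deterministic.
#'
#' @param embedding A [spectral_embed()] result, or a plain numeric matrix
#'   of coordinates (rows = patients).
#' @param C Number of clusters.
#' @param seed Integer seed controlling the k-means restarts.
#' @return A tibble of class `cluster_assignment` with columns `patient_id`
#'   and `cluster` (integers `1..C`, every cluster nonempty), carrying the
#'   embedding and `C` as attributes.
#' @export
cluster_embedding <- function(embedding, C, seed = 1L) {
  X <- if (inherits(embedding, "spectral_embedding")) embedding$rows else as.matrix(embedding)
  C <- as.integer(C)
  n <- nrow(X)
  if (C < 2L || C > n) stopf("`C` must be between 2 and n")
  km <- withr::with_seed(seed, {
    fit <- NULL
    for (attempt in 1:5) {
      fit <- tryCatch(
        stats::kmeans(X, centers = C, nstart = 25L, iter.max = 100L),
        error = function(e) NULL
      )
      if (!is.null(fit) && all(fit$size > 0)) break
    }
    fit
  })
  if (is.null(km) || any(km$size == 0)) stopf("k-means failed to produce %d nonempty clusters", C)
  labels <- km$cluster
  # relabel by descending cluster size (ties: original label order)
  sizes <- tabulate(labels, nbins = C)
  remap <- integer(C)
  remap[order(-sizes, seq_len(C))] <- seq_len(C)
  labels <- remap[labels]
  ids <- rownames(X) %||% as.character(seq_len(n))
  out <- tibble::tibble(patient_id = ids, cluster = as.integer(labels))
  class(out) <- c("cluster_assignment", class(out))
  attr(out, "C") <- C
  attr(out, "embedding") <- X
  out
}

#' Normalized-cut spectral clustering of a fused kernel
#'
#' Composition of [normalized_laplacian()], [spectral_embed()], and
#' [cluster_embedding()]: the standard pipeline for partitioning patients
#' from a symmetric affinity.
#'
#' @param K A symmetric nonnegative `similarity_kernel` (or matrix).
#' @param C Number of clusters, `2 <= C <= n - 1`.
#' @param seed Integer seed for the k-means step.
#' @return A `cluster_assignment` tibble (see [cluster_embedding()]).
#' @export
#' @examples
#' blocks <- kronecker(diag(2), matrix(1, 4, 4)) + 0.01
#' rownames(blocks) <- colnames(blocks) <- paste0("P", 1:8)
#' K <- similarity_kernel(blocks, kind = "fused")
#' spectral_cluster(K, C = 2, seed = 7)
spectral_cluster <- function(K, C, seed = 1L) {
  L <- normalized_laplacian(K)
  emb <- spectral_embed(L, C)
  cluster_embedding(emb, C, seed = seed)
}

#' Scan cluster numbers by survival separation
#'
#' Clusters the kernel at each candidate `C` and scores the resulting
#' partition with the multi-group log-rank test, reporting
#' `-log10(p)` so that better-separated survival profiles score higher.
#'
#' @param K A symmetric nonnegative `similarity_kernel`.
#' @param survival A [survival_table()] covering the kernel's patients.
#' @param C_range Integer vector of candidate cluster numbers (default 2:8).
#' @param seed Integer seed shared by all k-means runs.
#' @return A tibble of class `cluster_scan` with one row per `C`: columns
#'   `C`, `chi_square`, `df`, `p_value`, `neg_log10_p`.
#' @export
scan_clusters <- function(K, survival, C_range = 2:8, seed = 1L) {
  n <- nrow(as_kernel_matrix(K))
  C_range <- sort(unique(as.integer(C_range)))
  if (any(C_range < 2L) || any(C_range > n - 1L)) {
    stopf("`C_range` must lie within [2, n - 1]")
  }
  L <- normalized_laplacian(K)
  rows <- purrr::map(C_range, function(C) {
    assign <- cluster_embedding(spectral_embed(L, C), C, seed = seed)
    lr <- logrank_test(survival, assign)
    tibble::tibble(C = C, chi_square = lr$chi_square, df = lr$df,
                   p_value = lr$p_value, neg_log10_p = neglog10_p(lr$p_value))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cluster_scan", class(out))
  out
}
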