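KERNEL_KINDS <- c("distance", "similarity", "normalized", "sparse", "combined", "fused")

#' Construct a patient-by-patient kernel
#'
#' Wraps a square nonnegative matrix over an ordered patient list and tags
#' it with its role in the fusion pipeline. Each kind carries an invariant
#' that is checked on construction:
#' \describe{
#'   \item{distance}{symmetric, zero diagonal (squared Euclidean distances)}
#'   \item{similarity}{symmetric (larger = more similar)}
#'   \item{normalized}{every column sums to 1 (the full transition kernel P)}
#'   \item{sparse}{every row sums to 1 (the kNN-restricted diffusion kernel S)}
#'   \item{combined}{square nonnegative (view average before masking)}
#'   \item{fused}{symmetric nonnegative (final integrated kernel)}
#' }
#'
#' @param matrix Square numeric matrix, finite and nonnegative.
#' @param patient_ids Character identifiers, defaults to `rownames(matrix)`.
#' @param kind One of `r toString(KERNEL_KINDS)`.
#' @return An object of class `similarity_kernel`.
#' @export
similarity_kernel <- function(matrix, patient_ids = rownames(matrix), kind = "similarity") {
  kind <- match.arg(kind, KERNEL_KINDS)
  if (!is.matrix(matrix) || !is.numeric(matrix) || nrow(matrix) != ncol(matrix)) {
    stopf("kernel must be a square numeric matrix")
  }
  if (is.null(patient_ids)) stopf("kernel needs patient identifiers")
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != nrow(matrix)) stopf("patient_ids length does not match kernel size")
  if (any(!is.finite(matrix))) stopf("kernel contains non-finite entries")
  if (any(matrix < 0)) stopf("kernel contains negative entries")
  tol <- 1e-8
  if (kind %in% c("distance", "similarity", "fused")) {
    if (max(abs(matrix - t(matrix))) > 1e-10) stopf("'%s' kernel must be symmetric", kind)
  }
  if (kind == "distance" && max(abs(diag(matrix))) > 1e-10) {
    stopf("distance kernel must have a zero diagonal")
  }
  if (kind == "normalized" && max(abs(colSums(matrix) - 1)) > tol) {
    stopf("normalized kernel columns must sum to 1")
  }
  if (kind == "sparse" && max(abs(rowSums(matrix) - 1)) > tol) {
    stopf("sparse kernel rows must sum to 1")
  }
  dimnames(matrix) <- list(patient_ids, patient_ids)
  structure(list(matrix = matrix, kind = kind), class = "similarity_kernel")
}

#' @export
patient_ids.similarity_kernel <- function(x) rownames(x$matrix)

#' @export
as.matrix.similarity_kernel <- function(x, ...) x$matrix

#' @export
dim.similarity_kernel <- function(x) dim(x$matrix)

#' @export
print.similarity_kernel <- function(x, ...) {
  cat(sprintf("<similarity_kernel:%s> %d x %d patients\n", x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

as_kernel_matrix <- function(K) {
  if (inherits(K, "similarity_kernel")) K$matrix else K
}

#' Squared Euclidean distances between patients
#'
#' Computes `D[i, j] = (e_i - e_j)' (e_i - e_j)` over each patient's feature
#' vector. The view should be z-score normalized first so every feature
#' contributes on the same scale.
#'
#' @param view An [expression_view()] (normally the output of
#'   [zscore_normalize()]).
#' @return A `similarity_kernel` of kind `"distance"` (squared distances,
#'   symmetric, zero diagonal).
#' @export
pairwise_distance_kernel <- function(view) {
  m <- view$values
  sq <- rowSums(m^2)
  d <- outer(sq, sq, "+") - 2 * tcrossprod(m)
  d[d < 0] <- 0 # numerical negatives
  d <- (d + t(d)) / 2
  diag(d) <- 0
  similarity_kernel(d, patient_ids(view), kind = "distance")
}

#' k-nearest-neighbour sets under a similarity kernel
#'
#' For each patient, the set of the `k` most similar other patients plus the
#' patient itself (so every set has `k + 1` members). Ties are broken by
#' ascending patient index for reproducibility.
#'
#' @param K A `similarity_kernel` (larger = more similar) or plain matrix.
#' @param k Number of neighbours, `1 <= k <= n - 1`.
#' @return An object of class `knn_sets` with elements `sets` (list of
#'   integer vectors, self first), `k`, and `patient_ids`.
#' @export
knn_sets <- function(K, k) {
  m <- as_kernel_matrix(K)
  n <- nrow(m)
  k <- as.integer(k)
  if (k < 1L || k >= n) stopf("`k` must satisfy 1 <= k <= n - 1 (n = %d, k = %d)", n, k)
  sets <- lapply(seq_len(n), function(i) {
    row <- m[i, ]
    row[i] <- -Inf
    ord <- order(-row, seq_len(n)) # descending similarity, ties to smallest index
    c(i, ord[seq_len(k)])
  })
  structure(list(sets = sets, k = k, patient_ids = rownames(m)), class = "knn_sets")
}

# neighbour sets by smallest distance (used for the local scale of the
# exponential kernel, where the raw object is a distance matrix)
nearest_sets <- function(D, k) {
  m <- as_kernel_matrix(D)
  knn_sets(max(m) - m, k)
}

#' @export
print.knn_sets <- function(x, ...) {
  cat(sprintf("<knn_sets> %d patients, k = %d (sets of size k + 1)\n",
              length(x$sets), x$k))
  invisible(x)
}

#' Convert squared distances to a locally scaled similarity kernel
#'
#' The scaled exponential kernel of the similarity-network-fusion lineage:
#' `K[i, j] = exp(-D[i, j] / (mu * eps[i, j]))` with
#' `eps[i, j] = (m_i + m_j + D[i, j]) / 3`, where `m_i` is the mean
#' *squared* distance from patient i to its `k` nearest neighbours. Keeping
#' the local scale on the same (squared) scale as the numerator makes the
#' exponent dimensionless and O(1) at any feature dimensionality; the local
#' scale adapts the bandwidth to each patient's neighbourhood density.
#' Coincident neighbourhoods (zero scale) are floored at 1e-12.
#'
#' @param D A `similarity_kernel` of kind `"distance"`.
#' @param neighbors A [knn_sets()] built on distances (nearest patients);
#'   computed from `D` and `k` when `NULL`.
#' @param mu Positive bandwidth multiplier; sensible values lie in
#'   `[0.3, 0.8]` (default 0.5).
#' @param k Neighbourhood size used when `neighbors` is `NULL`.
#' @return A `similarity_kernel` of kind `"similarity"` with unit diagonal
#'   and entries in (0, 1].
#' @export
distance_to_similarity <- function(D, neighbors = NULL, mu = 0.5, k = NULL) {
  check_scalar(mu, "mu", lo = .Machine$double.eps)
  m <- as_kernel_matrix(D)
  n <- nrow(m)
  if (is.null(neighbors)) {
    if (is.null(k)) stopf("supply `neighbors` or `k`")
    neighbors <- nearest_sets(m, k)
  }
  mean_local <- vapply(seq_len(n), function(i) {
    nb <- setdiff(neighbors$sets[[i]], i)
    mean(m[i, nb])
  }, numeric(1))
  eps <- (outer(mean_local, mean_local, "+") + m) / 3
  if (any(eps <= 0)) {
    inform("distance_to_similarity: zero local scale floored at 1e-12")
    eps[eps <= 0] <- 1e-12
  }
  K <- exp(-m / (mu * eps))
  K <- (K + t(K)) / 2
  diag(K) <- 1
  similarity_kernel(K, rownames(m), kind = "similarity")
}

#' Column-normalize a kernel into a full transition kernel P
#'
#' `P[i, j] = K[i, j] / sum_k K[k, j]`; every column of P sums to 1, so P
#' acts like a transition-probability matrix over patients.
#'
#' @param K A nonnegative `similarity_kernel` (or matrix) whose columns all
#'   have positive sums.
#' @return A `similarity_kernel` of kind `"normalized"`.
#' @export
normalize_kernel <- function(K) {
  m <- as_kernel_matrix(K)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    bad <- rownames(m)[cs <= 0] %||% which(cs <= 0)
    stopf("zero column sum for patient(s): %s", toString(head(bad, 5)))
  }
  similarity_kernel(sweep(m, 2, cs, "/"), rownames(m), kind = "normalized")
}

#' Sparsify a kernel onto k-nearest-neighbour sets (the diffusion kernel S)
#'
#' `S[i, j] = K[i, j] / sum_{l in N_i} K[i, l]` for `j` in patient i's
#' neighbour set `N_i` (self included), and 0 elsewhere. Rows are
#' stochastic, so S propagates similarity only along strong local edges,
#' eliminating weak similarity.
#'
#' @param K A nonnegative `similarity_kernel` (or matrix).
#' @param neighbors A [knn_sets()] on the same patients.
#' @return A `similarity_kernel` of kind `"sparse"` with exactly `k + 1`
#'   nonzeros per row.
#' @export
sparsify_kernel <- function(K, neighbors) {
  m <- as_kernel_matrix(K)
  n <- nrow(m)
  if (length(neighbors$sets) != n) stopf("neighbor sets do not match kernel size")
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- neighbors$sets[[i]]
    s <- sum(m[i, nb])
    if (s <= 0) {
      bad <- rownames(m)[i] %||% i
      stopf("zero neighbourhood sum for patient %s", bad)
    }
    out[i, nb] <- m[i, nb] / s
  }
  similarity_kernel(out, rownames(m), kind = "sparse")
}
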