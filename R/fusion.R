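#' Cross-diffusion iteration over per-view kernels
#'
#' The core of similarity kernel fusion. Each view's full transition kernel
#' is repeatedly updated by diffusing the average of the *other* views'
#' current states through its own sparse kNN kernel, anchored to the initial
#' cross-view average:
#'
#' `P_l <- alpha * S_l %*% meanOthers(P^t) %*% t(S_l) +
#'         (1 - alpha) * meanOthers(P^0)`
#'
#' Updates are synchronous (all views computed from the t-state, then
#' applied) and each updated kernel is column re-normalized so the
#' transition-kernel invariant is preserved across iterations. At
#' `alpha = 0` the map has no diffusion term and reaches its fixed point
#' (the re-normalized initial cross-view average) after one iteration; at
#' `alpha = 1` nothing anchors the iteration to the initial state.
#'
#' @param P_list List of kind-`"normalized"` kernels, one per view (>= 2).
#' @param S_list List of kind-`"sparse"` kernels, same views, same patients.
#' @param alpha Diffusion weight in `[0, 1]`.
#' @param max_iters Maximum number of iterations (default 20).
#' @param tol Stop when the largest per-view relative Frobenius change
#'   falls below this (default 1e-6).
#' @return A list with `P_list` (kernels at the final state), `iterations_run`,
#'   `converged`, and `history` (per-iteration max relative change).
#' @export
skf_iterate <- function(P_list, S_list, alpha, max_iters = 20L, tol = 1e-6) {
  check_scalar(alpha, "alpha", 0, 1)
  check_scalar(max_iters, "max_iters", 1)
  check_scalar(tol, "tol", .Machine$double.xmin)
  L <- length(P_list)
  if (L < 2L || length(S_list) != L) {
    stopf("need the same number (>= 2) of P and S kernels, got %d and %d", L, length(S_list))
  }
  P0 <- lapply(P_list, as_kernel_matrix)
  S <- lapply(S_list, as_kernel_matrix)
  n <- nrow(P0[[1L]])
  for (m in c(P0, S)) {
    if (!all(dim(m) == n)) stopf("all kernels must share the same dimension")
  }
  ids <- rownames(P0[[1L]])

  mean_others <- function(mats, l) Reduce(`+`, mats[-l]) / (L - 1)
  anchor <- lapply(seq_len(L), function(l) (1 - alpha) * mean_others(P0, l))

  P <- P0
  history <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (t in seq_len(max_iters)) {
    P_new <- lapply(seq_len(L), function(l) {
      upd <- alpha * (S[[l]] %*% mean_others(P, l) %*% t(S[[l]])) + anchor[[l]]
      sweep(upd, 2, colSums(upd), "/")
    })
    change <- max(vapply(seq_len(L), function(l) {
      frobenius(P_new[[l]] - P[[l]]) / frobenius(P[[l]])
    }, numeric(1)))
    P <- P_new
    iterations <- t
    history <- c(history, change)
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  list(
    P_list = lapply(P, similarity_kernel, patient_ids = ids, kind = "normalized"),
    iterations_run = iterations,
    converged = converged,
    history = history
  )
}

#' Average per-view kernels into one combined kernel
#'
#' Elementwise mean of the per-view transition kernels at the end of the
#' cross-diffusion iteration.
#'
#' @param P_list Nonempty list of kernels (or matrices) of matching shape.
#' @return A `similarity_kernel` of kind `"combined"`.
#' @export
combine_kernels <- function(P_list) {
  if (!length(P_list)) stopf("`P_list` must be nonempty")
  mats <- lapply(P_list, as_kernel_matrix)
  n <- nrow(mats[[1L]])
  for (m in mats) if (!all(dim(m) == n)) stopf("kernels must share the same shape")
  similarity_kernel(Reduce(`+`, mats) / length(mats),
                    rownames(mats[[1L]]), kind = "combined")
}

#' Mutual k-nearest-neighbour weight matrix
#'
#' Noise mask for the combined kernel: weight 1 where two patients are in
#' each other's neighbour sets, 0.5 where the relation is one-way, and 0
#' where neither includes the other. Because every patient is in its own
#' set, the diagonal is 1, and the matrix is symmetric by construction.
#'
#' @param neighbors A [knn_sets()] (built on the combined kernel).
#' @return A numeric n-by-n matrix with entries in `{0, 0.5, 1}`.
#' @export
mutual_knn_weights <- function(neighbors) {
  n <- length(neighbors$sets)
  member <- matrix(0, n, n)
  for (i in seq_len(n)) member[i, neighbors$sets[[i]]] <- 1
  w <- (member + t(member)) / 2
  dimnames(w) <- list(neighbors$patient_ids, neighbors$patient_ids)
  w
}

#' Apply the mutual-neighbour mask and symmetrize
#'
#' `K* = w o K_com` (elementwise), followed by `(K* + t(K*)) / 2`. The final
#' average repairs the slight asymmetry that column normalization and
#' one-way neighbourhoods introduce, as spectral clustering needs a
#' symmetric affinity.
#'
#' @param K_com Combined kernel (kind `"combined"`) or matrix.
#' @param w Weight matrix from [mutual_knn_weights()].
#' @return A `similarity_kernel` of kind `"fused"`.
#' @export
apply_weights <- function(K_com, w) {
  m <- as_kernel_matrix(K_com)
  if (!all(dim(w) == dim(m))) stopf("weight matrix shape does not match kernel")
  masked <- w * m
  similarity_kernel((masked + t(masked)) / 2, rownames(m), kind = "fused")
}

#' Fusion parameters
#'
#' @param alpha Diffusion weight in `[0, 1]` (default 0.5). 0 keeps only the
#'   initial cross-view average; 1 keeps only the diffused information.
#' @param k Neighbourhood size; default `max(5, round(n / 10))`, capped at
#'   `n - 1`.
#' @param mu Bandwidth multiplier of the scaled exponential kernel
#'   (default 0.5, sensible range 0.3-0.8).
#' @param max_iters Maximum cross-diffusion iterations (default 20).
#' @param tol Relative Frobenius-change stopping threshold (default 1e-6).
#' @return A list of class `fusion_params`.
#' @export
fusion_params <- function(alpha = 0.5, k = NULL, mu = 0.5, max_iters = 20L, tol = 1e-6) {
  check_scalar(alpha, "alpha", 0, 1)
  if (!is.null(k)) check_scalar(k, "k", 1)
  check_scalar(mu, "mu", .Machine$double.eps)
  check_scalar(max_iters, "max_iters", 1)
  check_scalar(tol, "tol", .Machine$double.xmin)
  structure(list(alpha = alpha, k = k, mu = mu,
                 max_iters = as.integer(max_iters), tol = tol),
            class = "fusion_params")
}

default_k <- function(n) as.integer(min(max(5, round(n / 10)), n - 1))

#' Similarity kernel fusion of a multi-view cohort
#'
#' End-to-end fusion: per view, z-score normalization, squared Euclidean
#' distances, locally scaled exponential similarity, the full transition
#' kernel P (column-stochastic) and sparse kNN kernel S (row-stochastic);
#' then the cross-diffusion iteration ([skf_iterate()]), the cross-view
#' average ([combine_kernels()]), and the mutual-kNN mask
#' ([mutual_knn_weights()], recomputed on the combined kernel) with final
#' symmetrization ([apply_weights()]). Deterministic given its inputs.
#'
#' @param x A [cohort()] (or list of >= 2 [expression_view()]s sharing a
#'   patient order).
#' @param params A [fusion_params()] object; individual arguments below
#'   override its fields.
#' @param alpha,k,mu,max_iters,tol See [fusion_params()].
#' @param normalize Z-score normalize each view first (default `TRUE`;
#'   idempotent, so already-normalized views are unchanged).
#' @return An object of class `skf_fit` with elements `fused`
#'   (`similarity_kernel`, kind `"fused"`), `combined`, `weights`,
#'   `per_view_final`, `iterations_run`, `converged`, `history`, and
#'   `params`.
#' @export
#' @examples
#' sim <- simulate_cohort(synthetic_spec(n_patients = 30, n_clusters = 2,
#'   n_features = c(20, 20)), seed = 1)
#' fit <- skf(sim$cohort, alpha = 0.5)
#' fit
skf <- function(x, params = fusion_params(), alpha = NULL, k = NULL, mu = NULL,
                max_iters = NULL, tol = NULL, normalize = TRUE) {
  views <- if (inherits(x, "cohort")) x$views else cohort(x)$views
  p <- params
  p$alpha <- alpha %||% p$alpha
  p$k <- k %||% p$k
  p$mu <- mu %||% p$mu
  p$max_iters <- max_iters %||% p$max_iters
  p$tol <- tol %||% p$tol
  n <- length(patient_ids(views[[1L]]))
  p$k <- as.integer(p$k %||% default_k(n))
  if (p$k < 1L || p$k >= n) stopf("`k` must satisfy 1 <= k <= n - 1 (n = %d, k = %d)", n, p$k)

  P_list <- vector("list", length(views))
  S_list <- vector("list", length(views))
  for (i in seq_along(views)) {
    v <- if (normalize) zscore_normalize(views[[i]]) else views[[i]]
    D <- pairwise_distance_kernel(v)
    Ksim <- distance_to_similarity(D, neighbors = nearest_sets(D, p$k), mu = p$mu)
    P_list[[i]] <- normalize_kernel(Ksim)
    S_list[[i]] <- sparsify_kernel(Ksim, knn_sets(Ksim, p$k))
  }

  it <- skf_iterate(P_list, S_list, alpha = p$alpha,
                    max_iters = p$max_iters, tol = p$tol)
  K_com <- combine_kernels(it$P_list)
  w <- mutual_knn_weights(knn_sets(K_com, p$k))
  fused <- apply_weights(K_com, w)

  structure(list(
    fused = fused,
    combined = K_com,
    weights = w,
    per_view_final = it$P_list,
    iterations_run = it$iterations_run,
    converged = it$converged,
    history = it$history,
    params = p,
    view_names = names(views)
  ), class = "skf_fit")
}

#' @export
print.skf_fit <- function(x, ...) {
  cat(sprintf("<skf_fit> %d patients, %d views (%s)\n",
              nrow(x$fused$matrix), length(x$per_view_final), toString(x$view_names)))
  cat(sprintf("  alpha = %g, k = %d, mu = %g; %d iteration(s), %s\n",
              x$params$alpha, x$params$k, x$params$mu, x$iterations_run,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Extract the fused kernel from a fit
#' @param fit An `skf_fit`.
#' @return The fused `similarity_kernel`.
#' @export
fused_kernel <- function(fit) {
  if (!inherits(fit, "skf_fit")) stopf("`fit` must be an skf_fit")
  fit$fused
}
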