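#' Tidy the cross-diffusion convergence history
#'
#' @param x An `skf_fit`.
#' @param ... Unused.
#' @return A tibble with columns `iteration` and `relative_change`.
#' @export
tidy.skf_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$history), relative_change = x$history)
}

#' One-row summary of a fusion fit
#'
#' @param x An `skf_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_patients`, `n_views`, `alpha`, `k`, `mu`,
#'   `iterations_run`, `converged`.
#' @export
glance.skf_fit <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$fused$matrix),
    n_views = length(x$per_view_final),
    alpha = x$params$alpha,
    k = x$params$k,
    mu = x$params$mu,
    iterations_run = x$iterations_run,
    converged = x$converged
  )
}

#' One-row summary of a cluster assignment
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return A one-row tibble with `n_patients`, `C`, and the smallest and
#'   largest cluster sizes.
#' @export
glance.cluster_assignment <- function(x, ...) {
  sizes <- tabulate(x$cluster, nbins = attr(x, "C"))
  tibble::tibble(n_patients = nrow(x), C = attr(x, "C"),
                 min_cluster_size = min(sizes), max_cluster_size = max(sizes))
}
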