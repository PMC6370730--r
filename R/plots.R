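#' Plot Kaplan-Meier curves per cluster
#'
#' @param object A [km_curves()] tibble.
#' @param ... Unused.
#' @return A ggplot object (step curves, one colour per cluster).
#' @export
autoplot.km_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = factor(.data$cluster))) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = "Subtype") +
    ggplot2::theme_minimal()
}

#' Plot survival separation against the number of clusters
#'
#' @param object A [scan_clusters()] tibble.
#' @param ... Unused.
#' @return A ggplot object of `-log10(p)` versus `C`, with the 0.05
#'   significance level marked.
#' @export
autoplot.cluster_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$C, y = .data$neg_log10_p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = "Number of clusters", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Plot survival separation across the alpha sweep
#'
#' @param object An [alpha_scan()] tibble.
#' @param ... Unused.
#' @return A ggplot object of `-log10(p)` versus `alpha`.
#' @export
autoplot.alpha_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha, y = .data$neg_log10_p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = expression(alpha), y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a similarity kernel
#'
#' @param K A `similarity_kernel`.
#' @param assignment Optional `cluster_assignment`; when given, patients are
#'   ordered by cluster so block structure is visible.
#' @return A ggplot tile plot.
#' @export
plot_kernel <- function(K, assignment = NULL) {
  m <- as_kernel_matrix(K)
  ids <- rownames(m)
  if (!is.null(assignment)) {
    ord <- assignment$patient_id[order(assignment$cluster)]
    m <- m[ord, ord]
    ids <- ord
  }
  df <- tibble::tibble(
    row = factor(rep(ids, times = ncol(m)), levels = rev(ids)),
    col = factor(rep(ids, each = nrow(m)), levels = ids),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
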