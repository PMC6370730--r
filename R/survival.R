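match_survival <- function(survival, assignment) {
  if (!inherits(survival, "survival_table")) stopf("`survival` must be a survival_table")
  if (!all(c("patient_id", "cluster") %in% names(assignment))) {
    stopf("`assignment` must have patient_id and cluster columns")
  }
  idx <- match(assignment$patient_id, survival$patient_id)
  if (anyNA(idx)) {
    stopf("patient(s) missing from survival table: %s",
          toString(head(assignment$patient_id[is.na(idx)], 5)))
  }
  tibble::tibble(
    time = survival$time[idx],
    event = survival$event[idx],
    group = as.integer(assignment$cluster)
  )
}

#' Multi-group log-rank test of survival separation
#'
#' Tests whether the survival profiles of the clusters differ: at each
#' distinct event time, observed events per group are compared with their
#' hypergeometric expectation given the at-risk sets, and the accumulated
#' discrepancies form a chi-square statistic on `C - 1` degrees of freedom
#' (Mantel-Haenszel variance for ties). This is the score test of a Cox
#' model with the cluster label as a categorical covariate.
#'
#' @param survival A [survival_table()] covering the assigned patients.
#' @param assignment A `cluster_assignment` (or any data frame with
#'   `patient_id` and `cluster` columns); at least two nonempty groups and
#'   at least one observed event are required.
#' @return An object of class `logrank_test` with `chi_square`, `df`,
#'   `p_value`, `group_sizes`, `observed`, and `expected`. See [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' surv <- survival_table(paste0("P", 1:6), c(1, 2, 3, 10, 20, 30), rep(1, 6))
#' grp <- tibble::tibble(patient_id = paste0("P", 1:6), cluster = rep(1:2, each = 3))
#' logrank_test(surv, grp)
logrank_test <- function(survival, assignment) {
  d <- match_survival(survival, assignment)
  groups <- sort(unique(d$group))
  if (length(groups) < 2L) stopf("log-rank test needs at least 2 nonempty groups")
  if (sum(d$event) == 0L) stopf("no events observed")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(fit$n) - 1L
  chi <- unname(fit$chisq)
  structure(list(
    chi_square = chi,
    df = df,
    p_value = stats::pchisq(chi, df, lower.tail = FALSE),
    group_sizes = as.integer(fit$n),
    observed = as.numeric(fit$obs),
    expected = as.numeric(fit$exp),
    groups = groups
  ), class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("  group sizes: %s\n", toString(x$group_sizes)))
  invisible(x)
}

#' @export
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(group = x$groups, n = x$group_sizes,
                 observed = x$observed, expected = x$expected)
}

#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df,
                 p_value = x$p_value, neg_log10_p = neglog10_p(x$p_value))
}

#' Kaplan-Meier curves per cluster
#'
#' Product-limit survival estimates for each cluster; censored patients
#' leave the at-risk set without producing a step. A `time = 0` row with
#' survival 1 is included per group so curves plot from the origin.
#'
#' @inheritParams logrank_test
#' @return A tibble of class `km_curves` with columns `cluster`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_curves <- function(survival, assignment) {
  d <- match_survival(survival, assignment)
  if (any(tabulate(d$group) == 0L)) stopf("empty cluster in assignment")
  d$group <- factor(d$group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata <- if (is.null(fit$strata)) {
    rep(levels(d$group)[1L], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- tibble::tibble(
    cluster = as.integer(strata),
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  origin <- curves |>
    dplyr::distinct(.data$cluster) |>
    dplyr::mutate(time = 0, n_risk = tabulate(d$group)[.data$cluster],
                  n_event = 0, n_censor = 0, survival = 1)
  out <- dplyr::arrange(dplyr::bind_rows(origin, curves), .data$cluster, .data$time)
  class(out) <- c("km_curves", class(out))
  out
}

#' Minus log10 of a p-value
#'
#' The scale used to compare survival separation across cluster numbers and
#' fusion parameters: larger is more significant.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return `-log10(p)`, nonnegative.
#' @export
neglog10_p <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stopf("`p` must lie in (0, 1]")
  }
  -log10(p)
}
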