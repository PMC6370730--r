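#' Construct a multi-view cohort
#'
#' A cohort bundles two or more expression views that share the same ordered
#' patient list, plus (optionally) a survival table on those patients. Use
#' [align_cohort()] to build one from views with differing patient sets.
#'
#' @param views List of [expression_view()] objects with identical
#'   `patient_ids` in identical order (at least 2 views, at least 3 patients).
#' @param survival Optional [survival_table()] covering the same patients in
#'   the same order.
#' @return An object of class `cohort`.
#' @export
cohort <- function(views, survival = NULL) {
  if (!is.list(views) || length(views) < 2L) stopf("a cohort needs at least 2 views")
  ok <- vapply(views, inherits, logical(1), "expression_view")
  if (!all(ok)) stopf("all elements of `views` must be expression_view objects")
  ids <- patient_ids(views[[1L]])
  if (length(ids) < 3L) stopf("a cohort needs at least 3 patients, got %d", length(ids))
  for (v in views[-1L]) {
    if (!identical(patient_ids(v), ids)) {
      stopf("views do not share an identical ordered patient list; use align_cohort()")
    }
  }
  if (!is.null(survival)) {
    if (!inherits(survival, "survival_table")) stopf("`survival` must be a survival_table")
    if (!identical(survival$patient_id, ids)) {
      stopf("survival table does not match the views' patient list; use align_cohort()")
    }
  }
  names(views) <- vapply(views, function(v) v$view_name, character(1))
  structure(list(views = views, survival = survival), class = "cohort")
}

#' @export
patient_ids.cohort <- function(x) patient_ids(x$views[[1L]])

#' Number of patients in a cohort
#' @param x A `cohort`.
#' @return Integer patient count.
#' @export
n_patients <- function(x) length(patient_ids(x))

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d views (%s)%s\n",
              n_patients(x), length(x$views),
              toString(names(x$views)),
              if (is.null(x$survival)) "" else ", with survival"))
  invisible(x)
}

#' Align expression views (and survival) onto a common patient list
#'
#' Restricts every input to the intersection of their patient identifiers,
#' sorted lexicographically (byte order, locale-independent) for
#' determinism, and reports how many patients each input lost. Aligning an
#' already-aligned cohort is a no-op.
#'
#' @param views List of [expression_view()] objects, or an existing `cohort`.
#' @param survival Optional [survival_table()]; when given, its patients
#'   also constrain the intersection.
#' @return A [cohort()] on the common ordered patient list.
#' @export
#' @examples
#' v1 <- expression_view(matrix(rnorm(8), 4, 2,
#'   dimnames = list(c("a", "b", "c", "d"), c("f1", "f2"))), view_name = "x")
#' v2 <- expression_view(matrix(rnorm(8), 4, 2,
#'   dimnames = list(c("b", "c", "d", "e"), c("g1", "g2"))), view_name = "y")
#' align_cohort(list(v1, v2))
align_cohort <- function(views, survival = NULL) {
  if (inherits(views, "cohort")) {
    survival <- survival %||% views$survival
    views <- views$views
  }
  if (length(views) < 2L) stopf("alignment needs at least 2 views")
  id_sets <- lapply(views, patient_ids)
  common <- Reduce(intersect, id_sets)
  if (!is.null(survival)) common <- intersect(common, survival$patient_id)
  common <- sort_ids(common)
  if (length(common) < 3L) {
    stopf("only %d patient(s) shared across inputs; need at least 3", length(common))
  }
  for (i in seq_along(views)) {
    lost <- length(id_sets[[i]]) - length(common)
    if (lost > 0L) {
      inform(sprintf("align_cohort: view '%s' lost %d patient(s)", views[[i]]$view_name, lost))
    }
  }
  aligned_views <- lapply(views, function(v) {
    expression_view(v$values[common, , drop = FALSE], view_name = v$view_name)
  })
  aligned_surv <- NULL
  if (!is.null(survival)) {
    lost <- nrow(survival) - length(common)
    if (lost > 0L) inform(sprintf("align_cohort: survival table lost %d patient(s)", lost))
    idx <- match(common, survival$patient_id)
    aligned_surv <- survival_table(common, survival$time[idx], survival$event[idx])
  }
  cohort(aligned_views, aligned_surv)
}
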