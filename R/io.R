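detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read an expression table from delimited text
#'
#' Reads a TSV/CSV expression table whose first field is an identifier and
#' returns an [expression_view()] with patients in rows, whatever the file
#' orientation. Missing values are handled at load so the returned view is
#' complete: features with more than `max_missing` missing entries are
#' dropped, and remaining missing entries are imputed with the feature mean.
#'
#' @param path Path to the file.
#' @param orientation `"patients_in_rows"` (first column = patient ids,
#'   header = feature ids) or `"patients_in_columns"` (the transpose).
#' @param view_name Name for the view; defaults to the file name without
#'   extension.
#' @param delim Field delimiter; auto-detected between tab and comma when
#'   `NULL`.
#' @param max_missing Maximum tolerated fraction of missing entries per
#'   feature before the feature is dropped (default 0.2).
#' @return An `expression_view` with patients in rows.
#' @export
read_expression_tsv <- function(path,
                                orientation = c("patients_in_rows", "patients_in_columns"),
                                view_name = NULL,
                                delim = NULL,
                                max_missing = 0.2) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  delim <- delim %||% detect_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, na = c("", "NA"))
  if (ncol(df) < 2L) stopf("expression table needs an identifier column plus data: %s", path)
  ids <- as.character(df[[1L]])
  body <- df[-1L]
  bad <- names(body)[!vapply(body, is.numeric, logical(1))]
  if (length(bad)) {
    stopf("non-numeric values in column(s) %s of %s", toString(head(bad, 5)), path)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "patients_in_columns") m <- t(m)
  m <- impute_missing_matrix(m, max_missing)
  view_name <- view_name %||% sub("\\.[^.]*$", "", basename(path))
  expression_view(m, view_name = view_name)
}

# drop features with > max_missing fraction NA, mean-impute the rest
impute_missing_matrix <- function(m, max_missing) {
  na_frac <- colMeans(is.na(m))
  drop <- na_frac > max_missing
  if (any(drop)) {
    inform(sprintf("dropping %d feature(s) with > %.0f%% missing values",
                   sum(drop), 100 * max_missing))
    m <- m[, !drop, drop = FALSE]
  }
  if (anyNA(m)) {
    n_imputed <- sum(is.na(m))
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2L]]
    inform(sprintf("imputed %d missing entr%s with feature means",
                   n_imputed, if (n_imputed == 1L) "y" else "ies"))
  }
  m
}

#' Write an expression view to tab-separated text
#'
#' Inverse of [read_expression_tsv()] in `patients_in_rows` orientation:
#' first column `patient_id`, one column per feature.
#'
#' @param view An [expression_view()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(view, path) {
  df <- tibble::as_tibble(as.data.frame(view$values), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(patient_id = patient_ids(view)), df)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Construct a survival table
#'
#' Per-patient right-censored follow-up: a nonnegative time and a binary
#' event indicator (1 = event observed, 0 = censored).
#'
#' @param patient_id Character vector of unique patient identifiers.
#' @param time Nonnegative follow-up times (consistent units across the
#'   table, e.g. days).
#' @param event 0/1 event indicators.
#' @return A tibble of class `survival_table` with columns `patient_id`,
#'   `time`, `event`.
#' @export
survival_table <- function(patient_id, time, event) {
  patient_id <- as.character(patient_id)
  dup <- unique(patient_id[duplicated(patient_id)])
  if (length(dup)) stopf("duplicate patient_ids in survival table: %s", toString(head(dup, 5)))
  time <- as.numeric(time)
  if (anyNA(time) || any(time < 0)) stopf("survival `time` must be nonnegative and complete")
  event <- as.numeric(event)
  if (anyNA(event) || !all(event %in% c(0, 1))) stopf("`event` must be 0 (censored) or 1 (event)")
  out <- tibble::tibble(patient_id = patient_id, time = time, event = as.integer(event))
  class(out) <- c("survival_table", class(out))
  out
}

#' Read a clinical survival table from delimited text
#'
#' Rows with missing time or event are dropped (with a message); negative
#' times and event codes outside 0/1 (after optional recoding) are errors.
#'
#' @param path Path to the file.
#' @param time_col,event_col Names of the follow-up time and event columns.
#' @param id_col Name of the patient identifier column; defaults to the
#'   first column.
#' @param event_recode Optional named vector mapping raw event codes to 0/1,
#'   e.g. `c(dead = 1, alive = 0)`.
#' @param delim Field delimiter; auto-detected between tab and comma when
#'   `NULL`.
#' @return A [survival_table()].
#' @export
read_clinical_tsv <- function(path, time_col = "time", event_col = "event",
                              id_col = NULL, event_recode = NULL, delim = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  delim <- delim %||% detect_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, na = c("", "NA"))
  id_col <- id_col %||% names(df)[1L]
  for (col in c(id_col, time_col, event_col)) {
    if (!col %in% names(df)) stopf("column '%s' not found in %s", col, path)
  }
  time <- as.numeric(df[[time_col]])
  event_raw <- df[[event_col]]
  if (!is.null(event_recode)) {
    event <- unname(event_recode[as.character(event_raw)])
  } else {
    event <- suppressWarnings(as.numeric(event_raw))
  }
  keep <- !is.na(time) & !is.na(event)
  if (any(!keep)) {
    inform(sprintf("read_clinical_tsv: dropped %d row(s) with missing time or event", sum(!keep)))
  }
  time <- time[keep]; event <- event[keep]; ids <- as.character(df[[id_col]])[keep]
  if (any(time < 0)) stopf("negative survival time for patient(s): %s",
                           toString(head(ids[time < 0], 5)))
  if (!all(event %in% c(0, 1))) {
    stopf("event values outside {0,1} after recoding: %s",
          toString(head(unique(event_raw[keep][!event %in% c(0, 1)]), 5)))
  }
  survival_table(ids, time, event)
}
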