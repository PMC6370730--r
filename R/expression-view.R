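#' Construct an expression view
#'
#' An expression view is one omics layer measured on a cohort: a numeric
#' patients-by-features matrix together with unique patient and feature
#' identifiers. It is the unit of input for kernel construction; a study
#' typically supplies two or more views (e.g. gene, miRNA and isoform
#' expression) on the same patients.
#'
#' @param values Numeric matrix, patients in rows, features in columns.
#'   Must be finite with no missing entries; missing-value handling happens
#'   at load time (see [read_expression_tsv()]).
#' @param patient_ids Character vector of unique patient identifiers, one
#'   per row. Defaults to `rownames(values)`.
#' @param feature_ids Character vector of unique feature identifiers, one
#'   per column. Defaults to `colnames(values)`.
#' @param view_name Single string naming the view (e.g. `"mirna"`).
#'
#' @return An object of class `expression_view`.
#' @seealso [read_expression_tsv()], [zscore_normalize()]
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("P", 1:3), paste0("g", 1:4)))
#' expression_view(m, view_name = "genes")
expression_view <- function(values,
                            patient_ids = rownames(values),
                            feature_ids = colnames(values),
                            view_name = "view") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (is.null(patient_ids) || is.null(feature_ids)) {
    stopf("patient and feature identifiers are required (as arguments or dimnames)")
  }
  patient_ids <- as.character(patient_ids)
  feature_ids <- as.character(feature_ids)
  if (length(patient_ids) != nrow(values)) {
    stopf("length of `patient_ids` (%d) does not match rows of `values` (%d)",
          length(patient_ids), nrow(values))
  }
  if (length(feature_ids) != ncol(values)) {
    stopf("length of `feature_ids` (%d) does not match columns of `values` (%d)",
          length(feature_ids), ncol(values))
  }
  dup <- unique(patient_ids[duplicated(patient_ids)])
  if (length(dup)) stopf("duplicate patient_ids: %s", toString(head(dup, 5)))
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup)) stopf("duplicate feature_ids: %s", toString(head(dup, 5)))
  if (anyNA(values) || any(!is.finite(values))) {
    stopf("`values` must be finite with no missing entries")
  }
  dimnames(values) <- list(patient_ids, feature_ids)
  structure(
    list(values = values, view_name = as.character(view_name)[1]),
    class = "expression_view"
  )
}

#' Patient identifiers of an object
#'
#' @param x An `expression_view`, `similarity_kernel`, or `cohort`.
#' @return Character vector of patient identifiers, in the object's order.
#' @export
patient_ids <- function(x) UseMethod("patient_ids")

#' @export
patient_ids.expression_view <- function(x) rownames(x$values)

#' Feature identifiers of an expression view
#' @param x An `expression_view`.
#' @return Character vector of feature identifiers.
#' @export
feature_ids <- function(x) colnames(x$values)

#' @export
dim.expression_view <- function(x) dim(x$values)

#' @export
print.expression_view <- function(x, ...) {
  cat(sprintf("<expression_view> '%s': %d patients x %d features\n",
              x$view_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.expression_view <- function(x, ...) x$values

#' Tidy an expression view into long format
#'
#' @param x An `expression_view`.
#' @param ... Unused.
#' @return A tibble with columns `patient_id`, `feature_id`, `value`.
#' @export
as_tibble.expression_view <- function(x, ...) {
  tibble::tibble(
    patient_id = rep(rownames(x$values), times = ncol(x$values)),
    feature_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Z-score normalize an expression view
#'
#' Standardizes each feature across patients: `x' = (x - mean) / sd`, so
#' that features measured on different scales contribute comparably to
#' patient-patient distances. Constant features (zero sd) are mapped to
#' all-zeros and counted in a message.
#'
#' @param view An [expression_view()].
#' @param sd_method `"population"` (divide by n; default) or `"sample"`
#'   (divide by n-1).
#' @return A normalized `expression_view` of the same shape.
#' @export
#' @examples
#' v <- expression_view(matrix(c(1, 2, 3), 3, 1,
#'   dimnames = list(c("a", "b", "c"), "f")))
#' as.matrix(zscore_normalize(v))
zscore_normalize <- function(view, sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  m <- view$values
  n <- nrow(m)
  mu <- colMeans(m)
  centred <- sweep(m, 2, mu, "-")
  ss <- colSums(centred^2)
  denom <- if (sd_method == "population") n else max(n - 1L, 1L)
  s <- sqrt(ss / denom)
  constant <- s == 0
  if (any(constant)) {
    inform(sprintf("zscore_normalize: %d constant feature(s) set to zero in view '%s'",
                   sum(constant), view$view_name))
    s[constant] <- 1 # centred values are already zero there
  }
  out <- sweep(centred, 2, s, "/")
  expression_view(out, view_name = view$view_name)
}
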