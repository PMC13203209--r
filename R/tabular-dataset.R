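#' Tabular dataset container
#'
#' Lightweight container for a numeric feature matrix with a binary class
#' label per row and an explicit missingness mask. This is the currency of
#' every other function in the package: the synthesizer, the preprocessing
#' pipeline and the evaluation metrics all consume and produce
#' `tabular_dataset` objects.
#'
#' @param values Numeric N x d matrix. Missing cells are `NA`.
#' @param labels Length-N vector coercible to integer 0/1 (1 = positive
#'   class, e.g. the sepsis-analog class).
#' @param feature_names Character vector of d feature names; defaults to
#'   `colnames(values)` or `feat_1..feat_d`.
#' @param label_name Name used for the label column on CSV export.
#'
#' @return An object of class `tabular_dataset`: a list with elements
#'   `values` (matrix, `NA` for missing), `labels` (integer 0/1),
#'   `feature_names`, `label_name` and `missing` (logical mask of the same
#'   shape as `values`).
#'
#' @details N = 0 rows is permitted so that an empty synthetic set can be
#'   exported as a header-only CSV; every fitting operation in the package
#'   rejects empty input with its own error.
#'
#' @examples
#' ds <- tabular_dataset(matrix(rnorm(20), 10, 2), labels = rep(c(0, 1), 5))
#' ds
#' @export
tabular_dataset <- function(values, labels, feature_names = NULL,
                            label_name = "label") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !(is.numeric(values) || nrow(values) == 0L)) {
    stopf("`values` must be a numeric matrix")
  }
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  if (d < 1L) stopf("dataset needs at least one feature column")
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) feature_names <- sprintf("feat_%d", seq_len(d))
  if (length(feature_names) != d) {
    stopf("feature_names length (%d) does not match feature count (%d)",
          length(feature_names), d)
  }
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stopf("labels length (%d) does not match row count (%d)", length(labels), n)
  }
  if (n > 0L && !all(labels %in% c(0L, 1L))) {
    stopf("labels must be binary 0/1")
  }
  colnames(values) <- feature_names
  structure(
    list(
      values = values,
      labels = labels,
      feature_names = feature_names,
      label_name = label_name,
      missing = is.na(values)
    ),
    class = "tabular_dataset"
  )
}

#' @export
print.tabular_dataset <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf(
    "tabular_dataset: %d records x %d features (%d positive / %d negative)\n",
    n, ncol(x$values), sum(x$labels == 1L), sum(x$labels == 0L)
  ))
  miss <- sum(x$missing)
  if (miss > 0L) {
    cat(sprintf("  missing cells: %d (%.2f%%)\n", miss,
                100 * miss / length(x$missing)))
  }
  invisible(x)
}

#' @export
dim.tabular_dataset <- function(x) dim(x$values)

# Row subset preserving class and metadata.
subset_rows <- function(dataset, idx) {
  tabular_dataset(
    dataset$values[idx, , drop = FALSE],
    dataset$labels[idx],
    feature_names = dataset$feature_names,
    label_name = dataset$label_name
  )
}

assert_no_missing <- function(dataset, what = "this operation") {
  if (any(dataset$missing)) {
    stopf("%s requires a fully observed dataset; run apply_preprocessor() first",
          what)
  }
  invisible(dataset)
}
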