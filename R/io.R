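#' Read a tabular dataset from CSV
#'
#' Reads a header CSV with one row per subject, numeric feature columns
#' (empty field = missing) and one binary label column, and returns a
#' [tabular_dataset()]. Labels are mapped to 0/1 with `positive_label`
#' becoming 1.
#'
#' @param path Path to a CSV file (comma separator, `.` decimal, UTF-8).
#' @param label_column Name of the label column.
#' @param positive_label Value in the label column identifying the positive
#'   class; compared after coercion to character.
#'
#' @return A [tabular_dataset()].
#' @seealso [write_csv_dataset()]
#' @export
read_csv_dataset <- function(path, label_column = "label",
                             positive_label = 1) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = NULL, fileEncoding = "UTF-8")
  if (!label_column %in% names(raw)) {
    stopf("label column '%s' not found in %s", label_column, path)
  }
  if (nrow(raw) == 0L) stopf("no usable rows in %s", path)
  feat_cols <- setdiff(names(raw), label_column)
  if (length(feat_cols) == 0L) stopf("no feature columns in %s", path)

  values <- matrix(NA_real_, nrow(raw), length(feat_cols),
                   dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    cell <- raw[[feat_cols[j]]]
    obs <- !is.na(cell) & nzchar(trimws(cell))
    num <- suppressWarnings(as.numeric(cell[obs]))
    if (anyNA(num)) {
      bad <- which(obs)[which(is.na(num))[1L]]
      stopf("non-numeric value '%s' in column '%s', row %d",
            cell[bad], feat_cols[j], bad)
    }
    values[obs, j] <- num
  }

  lab_raw <- trimws(raw[[label_column]])
  lev <- unique(lab_raw)
  if (length(lev) > 2L) {
    stopf("label column '%s' has %d distinct values; expected at most 2",
          label_column, length(lev))
  }
  labels <- as.integer(lab_raw == as.character(positive_label))
  tabular_dataset(values, labels, feature_names = feat_cols,
                  label_name = label_column)
}

#' Write a tabular dataset to CSV
#'
#' Inverse of [read_csv_dataset()]: header row, feature columns first, label
#' column last, missing cells as empty fields. Floats are printed with 17
#' significant digits so that write/read round-trips are lossless.
#'
#' @param dataset A [tabular_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_csv_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "tabular_dataset"))
  vals <- dataset$values
  txt <- matrix("", nrow(vals), ncol(vals))
  obs <- !dataset$missing
  txt[obs] <- sprintf("%.17g", vals[obs])
  header <- c(dataset$feature_names, dataset$label_name)
  lines <- c(
    paste(header, collapse = ","),
    if (nrow(vals) > 0L) {
      paste(apply(cbind(txt, as.character(dataset$labels)), 1L,
                  paste, collapse = ","))
    }
  )
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stopf("cannot write to %s: %s",
                                            path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits a dataset into disjoint, exhaustive train and test parts,
#' stratified by class label. Per-class test counts are
#' `floor(test_fraction * n_class)`; the remainder stays in the training
#' part, so class ratios are stable across seeds.
#'
#' @param dataset A [tabular_dataset()] with both classes present.
#' @param test_fraction Proportion in (0, 1) assigned to the test part.
#' @param seed Integer seed making the split reproducible.
#' @return A list with elements `train` and `test`, both [tabular_dataset()].
#' @export
split_train_test <- function(dataset, test_fraction = 0.15, seed = 1) {
  stopifnot(inherits(dataset, "tabular_dataset"))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stopf("test_fraction must be in (0, 1)")
  }
  lab <- dataset$labels
  if (length(unique(lab)) < 2L) stopf("both classes must be present to split")
  test_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    rows <- which(lab == cls)
    n_test <- floor(test_fraction * length(rows))
    if (n_test < 1L || n_test >= length(rows)) {
      stopf("class %d has too few rows (%d) to appear in both parts",
            cls, length(rows))
    }
    test_idx <- c(test_idx,
                  with_seed(seed + cls, sample(rows, n_test)))
  }
  test_idx <- sort(test_idx)
  list(
    train = subset_rows(dataset, setdiff(seq_along(lab), test_idx)),
    test = subset_rows(dataset, test_idx)
  )
}
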