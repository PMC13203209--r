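#' Fit the median-imputation + z-score preprocessing pipeline
#'
#' Clinical tabular data arrive with missing cells and features on wildly
#' different scales (ages, lactate, platelet counts). The pipeline fitted
#' here fills missing cells with the per-feature median of the observed
#' training values — robust to the skewed distributions typical of
#' laboratory results — and then standardizes every feature to zero mean and
#' unit standard deviation. All statistics are computed on the training data
#' only and reused verbatim for test or external data, so no information
#' leaks across the split.
#'
#' @param train A [tabular_dataset()]; every feature must have at least one
#'   observed value and non-zero post-imputation variance.
#'
#' @return An object of class `tab_preprocess` holding per-feature `median`
#'   (original units), `mean` and `sd` (post-imputation, original units;
#'   sample convention, denominator N-1).
#'
#' @seealso [apply_preprocessor()], [invert_preprocessor()]
#' @export
fit_preprocessor <- function(train) {
  stopifnot(inherits(train, "tabular_dataset"))
  vals <- train$values
  if (nrow(vals) < 1L) stopf("cannot fit a preprocessor on an empty dataset")
  d <- ncol(vals)
  med <- numeric(d)
  for (j in seq_len(d)) {
    obs <- vals[, j][!train$missing[, j]]
    if (length(obs) == 0L) {
      stopf("feature '%s' has no observed values", train$feature_names[j])
    }
    med[j] <- stats::median(obs)
  }
  imputed <- vals
  for (j in seq_len(d)) imputed[train$missing[, j], j] <- med[j]
  mu <- colMeans(imputed)
  sdev <- apply(imputed, 2L, stats::sd)
  if (any(sdev <= 0)) {
    bad <- train$feature_names[which(sdev <= 0)[1L]]
    stopf("feature '%s' is constant after imputation", bad)
  }
  structure(
    list(median = med, mean = mu, sd = sdev,
         feature_names = train$feature_names, fitted = TRUE),
    class = "tab_preprocess"
  )
}

#' Impute and standardize a dataset with fitted training statistics
#'
#' Missing cells are replaced by the training median, then every feature is
#' transformed as `(x - mean) / sd` using the training mean and standard
#' deviation. The output has no missing cells.
#'
#' @param model A fitted `tab_preprocess` from [fit_preprocessor()].
#' @param data A [tabular_dataset()] with the same feature names.
#' @return A standardized [tabular_dataset()] with no missing cells.
#' @export
apply_preprocessor <- function(model, data) {
  check_preprocessor(model, data)
  vals <- data$values
  for (j in seq_len(ncol(vals))) {
    vals[data$missing[, j], j] <- model$median[j]
    vals[, j] <- (vals[, j] - model$mean[j]) / model$sd[j]
  }
  tabular_dataset(vals, data$labels, feature_names = data$feature_names,
                  label_name = data$label_name)
}

#' Map standardized records back to original units
#'
#' Applies `x * sd + mean` per feature, undoing [apply_preprocessor()] so
#' synthetic records can be exported on the original clinical scale.
#'
#' @inheritParams apply_preprocessor
#' @return A [tabular_dataset()] in original units.
#' @export
invert_preprocessor <- function(model, data) {
  check_preprocessor(model, data)
  vals <- data$values
  for (j in seq_len(ncol(vals))) {
    vals[, j] <- vals[, j] * model$sd[j] + model$mean[j]
  }
  tabular_dataset(vals, data$labels, feature_names = data$feature_names,
                  label_name = data$label_name)
}

check_preprocessor <- function(model, data) {
  if (!inherits(model, "tab_preprocess") || !isTRUE(model$fitted)) {
    stopf("`model` must be a fitted tab_preprocess")
  }
  stopifnot(inherits(data, "tabular_dataset"))
  if (!identical(model$feature_names, data$feature_names)) {
    stopf("feature names do not match the fitted preprocessor")
  }
  invisible(TRUE)
}

#' @export
print.tab_preprocess <- function(x, ...) {
  cat(sprintf("tab_preprocess: %d features (median imputation + z-score)\n",
              length(x$feature_names)))
  invisible(x)
}
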