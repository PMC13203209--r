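#' Fit the k-nearest-neighbour utility validator
#'
#' A lazy learner: the (preprocessed) reference set is stored verbatim and
#' queries are answered by majority vote among the k nearest reference
#' points by Euclidean distance. Within the synthesizer this classifier,
#' trained on the real training data, acts as the utility gate — synthetic
#' candidates whose predicted class differs from their intended class are
#' discarded as non-usable.
#'
#' @param train A fully observed [tabular_dataset()] with both classes.
#' @param k Number of neighbours, `1 <= k <= N`. Defaults to 5, the same
#'   neighbourhood size used by the density/coverage fidelity metrics.
#' @return An object of class `knn_model`.
#' @export
fit_knn <- function(train, k = 5) {
  stopifnot(inherits(train, "tabular_dataset"))
  assert_no_missing(train, "fit_knn()")
  n <- nrow(train$values)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n) {
    stopf("k must satisfy 1 <= k <= N (N = %d)", n)
  }
  if (length(unique(train$labels)) < 2L) {
    stopf("reference set contains a single class; validator is degenerate")
  }
  structure(
    list(reference = train$values, labels = train$labels, k = as.integer(k)),
    class = "knn_model"
  )
}

#' Predict classes with the KNN validator
#'
#' Ties are handled deterministically: neighbours are ordered by distance
#' with reference index as tie-breaker, and a tied vote (possible for even
#' k) is resolved to the class of the single nearest neighbour.
#'
#' @param object A `knn_model` from [fit_knn()].
#' @param query Numeric Q x d matrix (or length-d vector).
#' @param ... Unused.
#' @return Integer vector of length Q with predicted labels in \{0, 1\}.
#' @export
predict.knn_model <- function(object, query, ...) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as_values_matrix(query, "query")
  if (ncol(query) != ncol(object$reference)) {
    stopf("query dimension %d does not match reference dimension %d",
          ncol(query), ncol(object$reference))
  }
  k <- object$k
  ref <- object$reference
  lab <- object$labels
  tref <- t(ref)
  vapply(seq_len(nrow(query)), function(q) {
    d <- sqrt(colSums((tref - query[q, ])^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    pos <- sum(lab[nn])
    if (2L * pos > k) 1L else if (2L * pos < k) 0L else lab[nn[1L]]
  }, integer(1))
}

#' Screen synthetic candidates against their intended class
#'
#' @param model A `knn_model` from [fit_knn()].
#' @param candidates Numeric Q x d matrix of candidate records.
#' @param intended_label The class (0 or 1) the candidates are meant to
#'   represent.
#' @return Logical vector: `TRUE` where the validator agrees with the
#'   intended class (candidate kept).
#' @export
validate_candidates <- function(model, candidates, intended_label) {
  stopifnot(inherits(model, "knn_model"))
  intended_label <- as.integer(intended_label)
  if (!intended_label %in% c(0L, 1L)) stopf("intended_label must be 0 or 1")
  predict(model, candidates) == intended_label
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("knn_model: k = %d, %d reference points (%d pos / %d neg)\n",
              x$k, nrow(x$reference), sum(x$labels == 1L),
              sum(x$labels == 0L)))
  invisible(x)
}
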