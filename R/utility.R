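#' Area under the ROC curve by rank statistic
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, ties counted one half — the
#' Mann-Whitney identity. Computed from mid-ranks, not by plotting a curve.
#'
#' @param labels Binary 0/1 vector with both classes present.
#' @param scores Numeric vector of risk scores (higher = more positive).
#' @return Scalar AUC in \[0, 1\].
#' @examples
#' auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.2)) # 0.75
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stopf("lengths differ")
  if (anyNA(labels) || anyNA(scores)) stopf("missing values not allowed")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stopf("AUC undefined: both classes must be present")
  }
  rk <- rank(scores)
  (sum(rk[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nearest-centroid reference classifier
#'
#' A dependency-light classifier satisfying the plug-in contract of
#' [evaluate_tstr()]: `fit(x, y)` stores the two class centroids and
#' `score(fitted, x)` returns the margin
#' `||x - centroid_0|| - ||x - centroid_1||` (higher = positive class).
#' Intended as the in-package reference model for utility harness tests;
#' external classifiers (random forests, SVMs, boosted trees) attach
#' through the same contract.
#'
#' @return A list with elements `name`, `fit` and `score`.
#' @export
nearest_centroid_classifier <- function() {
  list(
    name = "nearest_centroid",
    fit = function(x, y) {
      y <- as.integer(y)
      if (length(unique(y)) < 2L) {
        stopf("nearest-centroid fit needs both classes")
      }
      list(mu0 = colMeans(x[y == 0L, , drop = FALSE]),
           mu1 = colMeans(x[y == 1L, , drop = FALSE]))
    },
    score = function(fitted, x) {
      dist_to_point(x, fitted$mu0) - dist_to_point(x, fitted$mu1)
    }
  )
}

#' Train-on-synthetic / test-on-real utility harness
#'
#' For each mixing fraction `f`, builds a training set of fixed total size
#' (the real training-set size) with `round(f * n)` synthetic rows and the
#' remainder real rows, subsampled without replacement under a
#' per-replicate seed; fits each classifier; scores the untouched real
#' test set; and reports the AUC. `f = 0` is the train-on-real baseline,
#' `f = 1` pure train-on-synthetic.
#'
#' @param train_real Real training [tabular_dataset()] (standardized).
#' @param synthetic Synthetic [tabular_dataset()] on the same scale.
#' @param test Held-out real [tabular_dataset()]; never used for fitting.
#' @param classifiers List of classifier contracts (see
#'   [nearest_centroid_classifier()]).
#' @param mixing_fractions Numeric vector of synthetic proportions in
#'   \[0, 1\].
#' @param replicates Number of repetitions with distinct seeds (default 3).
#' @param seed Base integer seed; replicate r uses `seed + r - 1`.
#' @return A data.frame with one row per (classifier, fraction, replicate):
#'   `classifier`, `fraction`, `replicate`, `n_train`, `auc`.
#' @seealso [summarize_tstr()]
#' @export
evaluate_tstr <- function(train_real, synthetic, test,
                          classifiers = list(nearest_centroid_classifier()),
                          mixing_fractions = c(0, 1),
                          replicates = 3, seed = 1) {
  for (ds in list(train_real, synthetic, test)) {
    stopifnot(inherits(ds, "tabular_dataset"))
    assert_no_missing(ds, "evaluate_tstr()")
  }
  if (!identical(train_real$feature_names, synthetic$feature_names) ||
      !identical(train_real$feature_names, test$feature_names)) {
    stopf("all sets must share the feature schema")
  }
  if (any(mixing_fractions < 0 | mixing_fractions > 1)) {
    stopf("mixing fractions must lie in [0, 1]")
  }
  n_total <- nrow(train_real$values)
  rows <- list()
  for (r in seq_len(replicates)) {
    rep_seed <- seed + r - 1L
    for (fi in seq_along(mixing_fractions)) {
      f <- mixing_fractions[fi]
      n_syn <- round(f * n_total)
      n_real <- n_total - n_syn
      if (n_syn > nrow(synthetic$values)) {
        stopf("fraction %.2f needs %d synthetic rows but only %d available",
              f, n_syn, nrow(synthetic$values))
      }
      idx_real <- with_seed(rep_seed * 131L + fi,
                            sample.int(n_total, n_real))
      idx_syn <- with_seed(rep_seed * 131L + fi + 65537L,
                           sample.int(nrow(synthetic$values), n_syn))
      x <- rbind(train_real$values[idx_real, , drop = FALSE],
                 synthetic$values[idx_syn, , drop = FALSE])
      y <- c(train_real$labels[idx_real], synthetic$labels[idx_syn])
      for (clf in classifiers) {
        fitted <- clf$fit(x, y)
        sc <- clf$score(fitted, test$values)
        rows[[length(rows) + 1L]] <- data.frame(
          classifier = clf$name, fraction = f, replicate = r,
          n_train = n_total, auc = auc_score(test$labels, sc)
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize utility-harness results across replicates
#'
#' @param results Output of [evaluate_tstr()].
#' @return A data.frame per (classifier, fraction) with `mean_auc` and
#'   `var_auc` across replicates.
#' @export
summarize_tstr <- function(results) {
  agg <- stats::aggregate(auc ~ classifier + fraction, data = results,
                          FUN = function(v) c(mean = mean(v),
                                              var = stats::var(v)))
  data.frame(
    classifier = agg$classifier,
    fraction = agg$fraction,
    mean_auc = agg$auc[, "mean"],
    var_auc = agg$auc[, "var"]
  )
}
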