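#' Per-feature two-sample Kolmogorov-Smirnov battery
#'
#' One two-sample KS test per feature (asymptotic p-values), comparing the
#' univariate synthetic distributions against the real ones, plus the mean
#' p-value across features as a single-number fidelity summary. High
#' p-values mean the synthetic marginals are statistically indistinguishable
#' from the real ones; note this is a marginal check only and says nothing
#' about the joint dependence structure.
#'
#' @param real,synthetic Numeric matrices (or [tabular_dataset()]s) with the
#'   same columns; at least 2 rows each.
#' @param feature_names Optional names; defaults to the columns of `real`.
#' @return A list with `table` (data.frame: feature, statistic, p_value) and
#'   `mean_p_value`.
#' @export
ks_battery <- function(real, synthetic, feature_names = NULL) {
  real <- as_values_matrix(real, "real")
  synthetic <- as_values_matrix(synthetic, "synthetic")
  if (ncol(real) != ncol(synthetic)) stopf("column counts differ")
  if (nrow(real) < 2L || nrow(synthetic) < 2L) {
    stopf("need at least 2 rows per set")
  }
  if (is.null(feature_names)) feature_names <- colnames(real)
  if (is.null(feature_names)) {
    feature_names <- sprintf("feat_%d", seq_len(ncol(real)))
  }
  res <- lapply(seq_len(ncol(real)), function(j) {
    kt <- suppressWarnings(
      stats::ks.test(real[, j], synthetic[, j], exact = FALSE))
    c(statistic = unname(kt$statistic), p_value = kt$p.value)
  })
  tab <- data.frame(
    feature = feature_names,
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_value = vapply(res, `[[`, numeric(1), "p_value")
  )
  list(table = tab, mean_p_value = mean(tab$p_value))
}

#' Density and coverage fidelity/diversity metrics
#'
#' k-nearest-neighbour ball metrics comparing a synthetic set against a
#' real one. Let `r_i` be the distance from real point `x_i` to its k-th
#' nearest *other* real point (closed ball, membership by `<=`). Then
#'
#' * density  = `1/(k*Q) * sum_j sum_i 1[ ||y_j - x_i|| <= r_i ]` —
#'   how densely the Q synthetic points populate the real neighbourhoods;
#'   not bounded by 1;
#' * coverage = fraction of real points whose ball contains at least one
#'   synthetic point — bounded in \[0, 1\]; a diversity measure.
#'
#' @param real Numeric N x d matrix, N > k.
#' @param synthetic Numeric Q x d matrix.
#' @param k Neighbourhood size (default 5).
#' @return A list with numeric scalars `density` and `coverage`.
#' @export
density_coverage <- function(real, synthetic, k = 5) {
  real <- as_values_matrix(real, "real")
  synthetic <- as_values_matrix(synthetic, "synthetic")
  if (anyNA(real) || anyNA(synthetic)) stopf("inputs must be fully observed")
  n <- nrow(real)
  q <- nrow(synthetic)
  if (n <= k) stopf("need more real points (N = %d) than k = %d", n, k)
  if (q < 1L) stopf("synthetic set is empty")
  if (ncol(real) != ncol(synthetic)) stopf("dimension mismatch")

  treal <- t(real)
  r <- vapply(seq_len(n), function(i) {
    di <- sqrt(colSums((treal - real[i, ])^2))
    sort(di[-i], partial = k)[k]
  }, numeric(1))

  inside_any <- logical(n)
  total <- 0
  for (j in seq_len(q)) {
    dj <- sqrt(colSums((treal - synthetic[j, ])^2))
    hit <- dj <= r
    total <- total + sum(hit)
    inside_any <- inside_any | hit
  }
  list(density = total / (k * q), coverage = mean(inside_any))
}

#' Dimension-wise moment comparison
#'
#' Per-feature sample means and variances of the real and synthetic sets,
#' with normal-approximation 95% confidence intervals on the means
#' (`mean +/- 1.96 * s / sqrt(n)`). Plotting `real_mean` against
#' `syn_mean` per feature is the usual agreement diagnostic: points on the
#' diagonal mean the synthetic set reproduces the univariate moments.
#'
#' @inheritParams ks_battery
#' @return A data.frame with one row per feature: means, variances and CI
#'   bounds for both sets.
#' @export
moment_comparison <- function(real, synthetic, feature_names = NULL) {
  real <- as_values_matrix(real, "real")
  synthetic <- as_values_matrix(synthetic, "synthetic")
  if (ncol(real) != ncol(synthetic)) stopf("column counts differ")
  if (nrow(real) < 2L || nrow(synthetic) < 2L) {
    stopf("need at least 2 rows per set")
  }
  if (is.null(feature_names)) feature_names <- colnames(real)
  if (is.null(feature_names)) {
    feature_names <- sprintf("feat_%d", seq_len(ncol(real)))
  }
  ci <- function(x) {
    m <- mean(x)
    hw <- 1.96 * stats::sd(x) / sqrt(length(x))
    c(m, stats::var(x), m - hw, m + hw)
  }
  rs <- apply(real, 2L, ci)
  ss <- apply(synthetic, 2L, ci)
  data.frame(
    feature = feature_names,
    real_mean = rs[1, ], real_var = rs[2, ],
    real_ci_lower = rs[3, ], real_ci_upper = rs[4, ],
    syn_mean = ss[1, ], syn_var = ss[2, ],
    syn_ci_lower = ss[3, ], syn_ci_upper = ss[4, ]
  )
}

#' Per-feature Mann-Whitney dataset-shift report
#'
#' Tests each feature for a distributional difference between two cohorts
#' with the two-sided Mann-Whitney U test (normal approximation with
#' continuity and tie correction), adjusting for multiple comparisons with
#' Bonferroni (`p_adj = min(1, d * p)`). A feature is flagged significant
#' at the conventional adjusted p < 0.01. Missing cells are excluded per
#' feature. The reported U statistic follows the `min(U1, U2)` convention.
#'
#' @param cohort_a,cohort_b Numeric matrices or [tabular_dataset()]s with
#'   matching columns; missing values allowed.
#' @param alpha Significance level on the adjusted p-value (default 0.01).
#' @return A data.frame with one row per feature: `U`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
shift_report <- function(cohort_a, cohort_b, alpha = 0.01) {
  a <- if (inherits(cohort_a, "tabular_dataset")) cohort_a$values
       else as_values_matrix(cohort_a, "cohort_a")
  b <- if (inherits(cohort_b, "tabular_dataset")) cohort_b$values
       else as_values_matrix(cohort_b, "cohort_b")
  if (ncol(a) != ncol(b)) stopf("column counts differ")
  d <- ncol(a)
  nms <- colnames(a)
  if (is.null(nms)) nms <- sprintf("feat_%d", seq_len(d))
  res <- lapply(seq_len(d), function(j) {
    x <- a[, j][!is.na(a[, j])]
    y <- b[, j][!is.na(b[, j])]
    if (length(x) == 0L || length(y) == 0L) {
      stopf("feature '%s' is empty in one cohort", nms[j])
    }
    n1 <- length(x)
    n2 <- length(y)
    rk <- rank(c(x, y))
    u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    u <- min(u1, n1 * n2 - u1)
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    c(U = u, p_value = p)
  })
  p_raw <- vapply(res, `[[`, numeric(1), "p_value")
  p_adj <- pmin(1, d * p_raw)
  data.frame(
    feature = nms,
    U = vapply(res, `[[`, numeric(1), "U"),
    p_value = p_raw,
    p_adjusted = p_adj,
    significant = p_adj < alpha
  )
}

#' One-call fidelity and privacy audit
#'
#' Convenience wrapper bundling the full metric suite for a synthetic set
#' against its real counterpart (both on the standardized scale): DCR
#' summaries ([dcr_real_real()], [dcr_synthetic()]), density/coverage,
#' the KS battery and the dimension-wise moment table.
#'
#' @param real,synthetic Fully observed matrices or [tabular_dataset()]s.
#' @param k Neighbourhood size for density/coverage (default 5).
#' @return A list of class `metric_report`.
#' @export
audit_synthetic <- function(real, synthetic, k = 5) {
  real_m <- as_values_matrix(real, "real")
  syn_m <- as_values_matrix(synthetic, "synthetic")
  dc <- density_coverage(real_m, syn_m, k = k)
  structure(
    list(
      dcr_real = dcr_real_real(real_m),
      dcr_synthetic = dcr_synthetic(syn_m, real_m),
      density = dc$density,
      coverage = dc$coverage,
      ks = ks_battery(real_m, syn_m),
      moments = moment_comparison(real_m, syn_m)
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report\n")
  cat(sprintf("  real-real mean DCR (sigma): %.4f\n", x$dcr_real$mean))
  cat(sprintf("  synthetic mean DCR:         %.4f (min %.4f)\n",
              x$dcr_synthetic$mean, min(x$dcr_synthetic$distances)))
  cat(sprintf("  density = %.4f, coverage = %.4f\n", x$density, x$coverage))
  cat(sprintf("  mean KS p-value over %d features: %.4f\n",
              nrow(x$ks$table), x$ks$mean_p_value))
  invisible(x)
}
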