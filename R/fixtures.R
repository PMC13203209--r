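#' Synthetic clinical fixture generator
#'
#' Emulates the statistical shape of an ICU sepsis cohort so the whole
#' pipeline is testable without access to protected hospital data: two
#' class-conditional multivariate Gaussians sharing an exchangeable
#' covariance, with configurable imbalance, between-class mean shift and
#' missing-completely-at-random cells. Defaults mirror a cohort of 1275
#' subjects (979 controls, 296 cases) measured on 27 continuous clinical
#' features with a weak class signal.
#'
#' @param n_control,n_case Records in the negative (label 0) and positive
#'   (label 1) class.
#' @param d Number of features (default 27).
#' @param effect Between-class mean shift: scalar or length-d vector;
#'   class-1 means are `effect`, class-0 means are 0 (before `noise_scale`).
#' @param correlation Exchangeable correlation `rho` in \[0, 1) or an
#'   explicit positive-definite d x d correlation matrix.
#' @param noise_scale Marginal standard deviation (default 1).
#' @param missing_rate MCAR missingness probability per cell in \[0, 1).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @param feature_names Optional feature names.
#' @return A [tabular_dataset()] with `n_control + n_case` rows (controls
#'   first), missing cells flagged.
#' @export
make_clinical_fixture <- function(n_control = 979, n_case = 296, d = 27,
                                  effect = 0.3, correlation = 0.3,
                                  noise_scale = 1, missing_rate = 0.05,
                                  seed = NULL, feature_names = NULL) {
  if (n_control < 0L || n_case < 0L) stopf("class counts must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    stopf("missing_rate must be in [0, 1)")
  }
  sigma <- fixture_covariance(d, correlation, noise_scale)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) stopf("correlation specification is not positive definite")
  mu1 <- rep(effect, length.out = d)
  n <- n_control + n_case
  if (is.null(feature_names)) feature_names <- sprintf("feat_%02d", seq_len(d))

  with_seed(seed, {
    z <- matrix(stats::rnorm(n * d), n, d) %*% ch
    z[seq_len(n_case) + n_control, ] <-
      sweep(z[seq_len(n_case) + n_control, , drop = FALSE], 2L, mu1, "+")
    if (missing_rate > 0) {
      z[matrix(stats::runif(n * d) < missing_rate, n, d)] <- NA_real_
    }
    tabular_dataset(z, labels = rep(c(0L, 1L), c(n_control, n_case)),
                    feature_names = feature_names)
  })
}

fixture_covariance <- function(d, correlation, noise_scale) {
  if (is.matrix(correlation)) {
    if (!all(dim(correlation) == d)) stopf("correlation matrix must be d x d")
    corr <- correlation
  } else {
    if (length(correlation) != 1L || correlation < 0 || correlation >= 1) {
      stopf("exchangeable correlation must lie in [0, 1)")
    }
    corr <- matrix(correlation, d, d)
    diag(corr) <- 1
  }
  noise_scale^2 * corr
}

#' Pair of cohorts with a controlled distribution shift
#'
#' Draws two cohorts from the same class-conditional Gaussian family, the
#' second with every class mean offset by `shift` — a stand-in for the
#' hospital-to-hospital dataset shift that external-validation studies face.
#' `shift = 0` yields a null pair for calibrating [shift_report()].
#'
#' @inheritParams make_clinical_fixture
#' @param shift Per-feature mean offset of cohort B: scalar or length-d.
#' @return A list with [tabular_dataset()] elements `a` and `b`.
#' @export
make_shifted_pair <- function(shift = 0, n_control = 979, n_case = 296,
                              d = 27, effect = 0.3, correlation = 0.3,
                              noise_scale = 1, missing_rate = 0.05,
                              seed = NULL) {
  shift <- rep(shift, length.out = d)
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  a <- make_clinical_fixture(n_control, n_case, d, effect, correlation,
                             noise_scale, missing_rate, seed = base_seed)
  b <- make_clinical_fixture(n_control, n_case, d, effect, correlation,
                             noise_scale, missing_rate,
                             seed = if (is.null(base_seed)) NULL
                                    else base_seed + 1L)
  obs <- !b$missing
  vals <- b$values
  vals <- vals + matrix(shift, nrow(vals), d, byrow = TRUE)
  vals[!obs] <- NA_real_
  b <- tabular_dataset(vals, b$labels, feature_names = b$feature_names,
                       label_name = b$label_name)
  list(a = a, b = b)
}
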