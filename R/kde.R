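#' Scott's rule bandwidth
#'
#' Bandwidth for a multivariate Gaussian kernel density estimate on
#' standardized data: `h = L^(-1/(d+4))` with `L` support points in `d`
#' dimensions. Because features are z-scored upstream, the per-feature scale
#' factor is 1 and the rule reduces to this pure size/dimension term.
#'
#' @param L Number of support points (>= 1).
#' @param d Dimension (>= 1).
#' @return A positive scalar bandwidth.
#' @examples
#' scott_bandwidth(256, 4) # 0.5
#' @export
scott_bandwidth <- function(L, d) {
  if (length(L) != 1L || is.na(L) || L < 1L) stopf("L must be a count >= 1")
  if (length(d) != 1L || is.na(d) || d < 1L) stopf("d must be a count >= 1")
  L^(-1 / (d + 4))
}

#' Fit a multivariate Gaussian kernel density estimate
#'
#' Represents the density as an equal-weight mixture of Gaussian kernels
#' centred at the support points:
#' `p(x) = 1/(L h^d) * sum_i K((x - x_i)/h)` with
#' `K(u) = (2*pi)^(-d/2) exp(-||u||^2 / 2)`.
#'
#' Two kernel geometries are available. The default, `"isotropic"`, uses a
#' single scalar bandwidth `h` in every direction — appropriate because the
#' generator operates on z-scored features where scales are comparable. In
#' `"covariance_scaled"` mode the kernel is shaped by the empirical support
#' covariance (regularized by `eps*I`, `eps = 1e-8 * trace/d`), i.e. kernel
#' covariance `h^2 * Sigma`, which is the common textbook pairing with
#' Scott's rule.
#'
#' @param points Numeric L x d support matrix with finite entries.
#' @param bandwidth Optional positive scalar overriding Scott's rule.
#' @param kernel_mode `"isotropic"` (default) or `"covariance_scaled"`.
#' @return An object of class `kde` with elements `support`, `h`, `d`, `L`,
#'   `kernel_mode`, and in covariance-scaled mode the Cholesky factor of the
#'   regularized support covariance.
#' @seealso [log_density()], [sample_kde()], [scott_bandwidth()]
#' @export
fit_kde <- function(points, bandwidth = NULL,
                    kernel_mode = c("isotropic", "covariance_scaled")) {
  kernel_mode <- match.arg(kernel_mode)
  points <- as_values_matrix(points, "points")
  if (nrow(points) < 1L) stopf("empty support")
  if (!all(is.finite(points))) stopf("support contains non-finite values")
  L <- nrow(points)
  d <- ncol(points)
  if (!is.null(bandwidth)) {
    if (!(length(bandwidth) == 1L && is.finite(bandwidth) && bandwidth > 0)) {
      stopf("bandwidth override must be a positive scalar")
    }
    h <- as.numeric(bandwidth)
  } else {
    h <- scott_bandwidth(L, d)
  }
  model <- list(support = points, h = h, d = d, L = L,
                kernel_mode = kernel_mode)
  if (kernel_mode == "covariance_scaled") {
    sigma <- stats::cov(points)
    if (anyNA(sigma)) stopf("support covariance undefined (L < 2?)")
    eps <- 1e-8 * sum(diag(sigma)) / d
    sigma <- sigma + diag(eps, d)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      stopf("support covariance is singular even after regularization")
    }
    model$chol_sigma <- ch # upper triangular: Sigma = t(ch) %*% ch
    model$log_det_sigma <- 2 * sum(log(diag(ch)))
  }
  structure(model, class = "kde")
}

#' @export
print.kde <- function(x, ...) {
  cat(sprintf("kde: %d support points, d = %d, h = %.6g (%s kernel)\n",
              x$L, x$d, x$h, x$kernel_mode))
  invisible(x)
}

#' Evaluate the log-density of a fitted KDE
#'
#' Computed with the log-sum-exp trick so queries far from all support
#' points return a finite (very negative) log-density instead of
#' underflowing to `-Inf`.
#'
#' @param model A fitted [fit_kde()] object.
#' @param query Numeric Q x d matrix (or length-d vector) of query points.
#' @return Length-Q numeric vector of log p(x).
#' @export
log_density <- function(model, query) {
  stopifnot(inherits(model, "kde"))
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as_values_matrix(query, "query")
  if (ncol(query) != model$d) {
    stopf("query dimension %d does not match model dimension %d",
          ncol(query), model$d)
  }
  h <- model$h
  d <- model$d
  if (model$kernel_mode == "covariance_scaled") {
    # whiten: u = solve(t(chol))(x - xi) / h; normalizer gains -log det term
    w_support <- t(backsolve(model$chol_sigma, t(model$support),
                             transpose = TRUE))
    w_query <- t(backsolve(model$chol_sigma, t(query), transpose = TRUE))
    extra <- -0.5 * model$log_det_sigma
  } else {
    w_support <- model$support
    w_query <- query
    extra <- 0
  }
  const <- -0.5 * d * log(2 * pi) - log(model$L) - d * log(h) + extra
  ts <- t(w_support)
  vapply(seq_len(nrow(w_query)), function(q) {
    sq <- colSums((ts - w_query[q, ])^2) / h^2
    const + logsumexp(-0.5 * sq)
  }, numeric(1))
}

#' Draw samples from a fitted KDE
#'
#' Exact mixture sampling: pick a support point uniformly at random, then
#' add kernel noise (`h * z` with `z` standard normal in isotropic mode;
#' covariance-shaped noise otherwise). Component indices are drawn before
#' the noise so the stream is reproducible for a given seed.
#'
#' @param model A fitted [fit_kde()] object.
#' @param n Number of samples (>= 0).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return An n x d numeric matrix.
#' @export
sample_kde <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "kde"))
  if (length(n) != 1L || is.na(n) || n < 0) stopf("n must be a count >= 0")
  n <- as.integer(n)
  d <- model$d
  if (n == 0L) {
    return(matrix(numeric(0), 0L, d,
                  dimnames = list(NULL, colnames(model$support))))
  }
  with_seed(seed, {
    idx <- sample.int(model$L, n, replace = TRUE)
    z <- matrix(stats::rnorm(n * d), n, d)
    noise <- if (model$kernel_mode == "covariance_scaled") {
      model$h * (z %*% model$chol_sigma)
    } else {
      model$h * z
    }
    out <- model$support[idx, , drop = FALSE] + noise
    dimnames(out) <- list(NULL, colnames(model$support))
    out
  })
}
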