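# Internal numeric helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Euclidean distances from every row of matrix X to the single point q.
# Summation runs over features in column order, matching a naive
# sqrt(sum((x - q)^2)) evaluation bit-for-bit.
dist_to_point <- function(X, q) {
  sqrt(colSums((t(X) - q)^2))
}

# Full Q x N cross-distance matrix: rows of A against rows of B.
cross_distances <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  tB <- t(B)
  for (j in seq_len(nrow(A))) {
    out[j, ] <- sqrt(colSums((tB - A[j, ])^2))
  }
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

as_values_matrix <- function(x, arg = "x") {
  if (inherits(x, "tabular_dataset")) {
    return(x$values)
  }
  if (is.data.frame(x)) {
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("`%s` must be a numeric matrix or a tabular_dataset", arg)
  }
  x
}
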