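# Brute-force oracles and small fixture builders shared across test files.
# Oracles deliberately use different code paths (stats::dist, scalar double
# loops, full sorts) from the package implementations they check.

# nearest-other-record distances within X, via stats::dist
oracle_dcr_real_real <- function(X) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  unname(apply(D, 1L, min))
}

# per-synthetic-row distance to the closest real row
oracle_dcr_synthetic <- function(S, X) {
  q <- nrow(S)
  D <- as.matrix(stats::dist(rbind(S, X)))[seq_len(q), q + seq_len(nrow(X)),
                                           drop = FALSE]
  unname(apply(D, 1L, min))
}

# KNN majority vote with the package's documented tie rules, from a
# dist()-derived distance matrix and a full order() sort
oracle_knn_predict <- function(ref, lab, k, query) {
  q <- nrow(query)
  D <- as.matrix(stats::dist(rbind(query, ref)))[seq_len(q),
                                                 q + seq_len(nrow(ref)),
                                                 drop = FALSE]
  vapply(seq_len(q), function(i) {
    nn <- order(D[i, ], seq_len(ncol(D)))[seq_len(k)]
    pos <- sum(lab[nn])
    if (2L * pos > k) 1L else if (2L * pos < k) 0L else lab[nn[1L]]
  }, integer(1))
}

# density & coverage by explicit nested indicator loops
oracle_density_coverage <- function(real, syn, k) {
  n <- nrow(real)
  q <- nrow(syn)
  rr <- as.matrix(stats::dist(real))
  r <- vapply(seq_len(n), function(i) sort(rr[i, -i])[k], numeric(1))
  cross <- as.matrix(stats::dist(rbind(syn, real)))[seq_len(q),
                                                    q + seq_len(n),
                                                    drop = FALSE]
  total <- 0L
  covered <- logical(n)
  for (j in seq_len(q)) {
    for (i in seq_len(n)) {
      if (cross[j, i] <= r[i]) {
        total <- total + 1L
        covered[i] <- TRUE
      }
    }
  }
  list(density = total / (k * q), coverage = mean(covered))
}

# AUC by exhaustive positive-negative pair counting, ties worth 1/2
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (g in neg) {
      total <- total + if (p > g) 1 else if (p == g) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# small standardized two-class dataset for generator-level tests
make_std_train <- function(n0 = 60, n1 = 30, d = 3, effect = 2, seed = 1) {
  ds <- make_clinical_fixture(n_control = n0, n_case = n1, d = d,
                              effect = effect, correlation = 0,
                              missing_rate = 0, seed = seed)
  apply_preprocessor(fit_preprocessor(ds), ds)
}

rand_matrix <- function(n, d) matrix(stats::rnorm(n * d), n, d)
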