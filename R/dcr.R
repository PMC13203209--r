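#' Real-to-real distance to closest record (the sigma reference)
#'
#' For every record, the Euclidean distance to its nearest *other* record
#' in the same set. The mean of these nearest-neighbour distances is the
#' sigma reference used by the generator's privacy filter: a synthetic
#' record must keep at least this distance (times a configurable
#' multiplier) from every real record. Distances are meaningful only on
#' standardized features; compute this where generation happens.
#'
#' @param X Numeric N x d matrix (N >= 2) or fully observed
#'   [tabular_dataset()].
#' @return An object of class `dcr_report` with elements `distances`
#'   (length-N vector), `mean` (the sigma reference) and `type`.
#' @seealso [dcr_synthetic()]
#' @export
dcr_real_real <- function(X) {
  X <- as_values_matrix(X, "X")
  if (anyNA(X)) stopf("X must be fully observed")
  n <- nrow(X)
  if (n < 2L) stopf("need at least 2 records to compute nearest-record distances")
  tX <- t(X)
  dist <- vapply(seq_len(n), function(j) {
    dj <- sqrt(colSums((tX - X[j, ])^2))
    min(dj[-j])
  }, numeric(1))
  new_dcr_report(dist, type = "real_vs_real")
}

#' Synthetic-to-real distance to closest record
#'
#' For each synthetic record, the Euclidean distance to the closest real
#' record (self-exclusion does not apply: the minimum runs over all real
#' records). Low values mean the synthetic record nearly replicates a real
#' subject — a privacy hazard; higher values indicate genuinely new records.
#'
#' @param S Numeric Q x d matrix of synthetic records (or
#'   [tabular_dataset()]).
#' @param X Numeric N x d matrix of real records (or [tabular_dataset()]).
#' @return A `dcr_report` with one distance per synthetic record.
#' @export
dcr_synthetic <- function(S, X) {
  S <- as_values_matrix(S, "S")
  X <- as_values_matrix(X, "X")
  if (anyNA(S) || anyNA(X)) stopf("inputs must be fully observed")
  if (nrow(X) < 1L) stopf("real set is empty")
  if (nrow(S) < 1L) stopf("synthetic set is empty")
  if (ncol(S) != ncol(X)) {
    stopf("dimension mismatch: synthetic d = %d, real d = %d",
          ncol(S), ncol(X))
  }
  tX <- t(X)
  dist <- vapply(seq_len(nrow(S)), function(j) {
    min(sqrt(colSums((tX - S[j, ])^2)))
  }, numeric(1))
  new_dcr_report(dist, type = "synthetic_vs_real")
}

new_dcr_report <- function(distances, type) {
  structure(
    list(distances = distances, mean = mean(distances), type = type),
    class = "dcr_report"
  )
}

#' @export
print.dcr_report <- function(x, ...) {
  cat(sprintf("dcr_report (%s): %d records, mean DCR = %.4f, min = %.4f\n",
              x$type, length(x$distances), x$mean, min(x$distances)))
  invisible(x)
}

#' Normalized histogram of a DCR distribution
#'
#' Density-scaled histogram (total area 1) of the per-record distances in a
#' `dcr_report`, the standard visual for comparing the privacy profile of a
#' synthetic set against the real-to-real baseline.
#'
#' @param report A `dcr_report`.
#' @param bins Number of equal-width bins (>= 1).
#' @return A list with `breaks`, `density` (per-bin density, integrates to
#'   1) and `counts`.
#' @export
dcr_distribution <- function(report, bins = 30) {
  stopifnot(inherits(report, "dcr_report"))
  if (length(report$distances) == 0L) stopf("empty DCR report")
  if (bins < 1L) stopf("bins must be >= 1")
  x <- report$distances
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  hh <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(breaks = hh$breaks, density = hh$density, counts = hh$counts)
}
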