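#' Fit the KDE-KNN synthesizer
#'
#' Fits every component of the privacy-aware synthetic data generator on a
#' preprocessed (imputed, z-scored) training set:
#'
#' 1. a k-nearest-neighbour classifier on the full training data — the
#'    utility validator;
#' 2. the class partition into positive (e.g. sepsis) and negative records;
#' 3. one multivariate Gaussian KDE per class, bandwidth by Scott's rule
#'    unless overridden;
#' 4. the sigma reference: the mean nearest-record distance within the
#'    training data, whose multiple sets the minimum distance any synthetic
#'    record must keep from every real record.
#'
#' Use [simulate()] on the returned object to generate synthetic records.
#'
#' @param data A fully observed, standardized [tabular_dataset()] with both
#'   classes present and at least 2 records per class.
#' @param k Neighbourhood size of the utility validator (default 5).
#' @param kernel_mode Kernel geometry passed to [fit_kde()]: `"isotropic"`
#'   scalar bandwidth (default, appropriate on z-scored features) or
#'   `"covariance_scaled"`.
#' @param bandwidth Optional bandwidth override: a single positive scalar
#'   for both classes or a length-2 vector `(positive, negative)`. `NULL`
#'   (default) selects Scott's rule per class.
#' @param sigma_multiplier Non-negative multiple of the sigma reference used
#'   as the privacy threshold (default 1: a synthetic record must lie at
#'   least one mean nearest-record distance from all real records).
#'
#' @return An object of class `kdeknn` with components `knn`, `kde_pos`,
#'   `kde_neg`, `sigma`, `sigma_multiplier`, `class_counts`, `train` and
#'   `feature_names`.
#'
#' @examples
#' ds <- make_clinical_fixture(n_control = 60, n_case = 30, d = 4,
#'                             missing_rate = 0, seed = 1)
#' prep <- fit_preprocessor(ds)
#' fit <- kdeknn(apply_preprocessor(prep, ds))
#' fit
#' syn <- simulate(fit, nsim = c(20, 20), seed = 7)
#' attr(syn, "report")
#' @export
kdeknn <- function(data, k = 5,
                   kernel_mode = c("isotropic", "covariance_scaled"),
                   bandwidth = NULL, sigma_multiplier = 1) {
  kernel_mode <- match.arg(kernel_mode)
  stopifnot(inherits(data, "tabular_dataset"))
  assert_no_missing(data, "kdeknn()")
  if (!(length(sigma_multiplier) == 1L && is.finite(sigma_multiplier) &&
        sigma_multiplier >= 0)) {
    stopf("sigma_multiplier must be a non-negative scalar")
  }
  parts <- partition_by_class(data)
  if (nrow(parts$positive$values) < 2L || nrow(parts$negative$values) < 2L) {
    stopf("each class needs at least 2 records to fit its KDE")
  }
  if (!is.null(bandwidth)) {
    if (!length(bandwidth) %in% c(1L, 2L) || any(!is.finite(bandwidth)) ||
        any(bandwidth <= 0)) {
      stopf("bandwidth must be one or two positive scalars")
    }
    bandwidth <- rep(as.numeric(bandwidth), length.out = 2L)
  }
  kde_pos <- fit_kde(parts$positive$values,
                     bandwidth = if (!is.null(bandwidth)) bandwidth[1L],
                     kernel_mode = kernel_mode)
  kde_neg <- fit_kde(parts$negative$values,
                     bandwidth = if (!is.null(bandwidth)) bandwidth[2L],
                     kernel_mode = kernel_mode)
  structure(
    list(
      knn = fit_knn(data, k = k),
      kde_pos = kde_pos,
      kde_neg = kde_neg,
      sigma = dcr_real_real(data$values)$mean,
      sigma_multiplier = sigma_multiplier,
      kernel_mode = kernel_mode,
      class_counts = c(positive = nrow(parts$positive$values),
                       negative = nrow(parts$negative$values)),
      train = data,
      feature_names = data$feature_names,
      call = match.call()
    ),
    class = "kdeknn"
  )
}

#' Partition a dataset by class label
#'
#' @param train A [tabular_dataset()] with both classes present.
#' @return List with elements `positive` (label 1) and `negative` (label 0),
#'   both [tabular_dataset()]; their rows union to the input.
#' @export
partition_by_class <- function(train) {
  stopifnot(inherits(train, "tabular_dataset"))
  pos <- which(train$labels == 1L)
  neg <- which(train$labels == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stopf("both classes must be present")
  }
  list(positive = subset_rows(train, pos), negative = subset_rows(train, neg))
}

#' @export
print.kdeknn <- function(x, ...) {
  cat("KDE-KNN synthesizer\n")
  cat(sprintf("  training records: %d (%d positive / %d negative)\n",
              sum(x$class_counts), x$class_counts["positive"],
              x$class_counts["negative"]))
  cat(sprintf("  kernel: %s; h = %.4f (pos), %.4f (neg)\n",
              x$kernel_mode, x$kde_pos$h, x$kde_neg$h))
  cat(sprintf("  validator: KNN, k = %d\n", x$knn$k))
  cat(sprintf("  sigma reference = %.4f; privacy threshold = %.4f\n",
              x$sigma, x$sigma * x$sigma_multiplier))
  invisible(x)
}

#' @export
summary.kdeknn <- function(object, ...) {
  print(object)
  cat(sprintf("  features: %s%s\n",
              paste(utils::head(object$feature_names, 5L), collapse = ", "),
              if (length(object$feature_names) > 5L) ", ..." else ""))
  invisible(object)
}

# Deterministic per-(class, iteration) seed so the per-class sampling
# streams are reproducible and, with both validations off, the output
# equals plain sample_kde() draws under the derived seed.
child_seed <- function(seed, class_index, iteration) {
  as.integer((as.double(seed) + 97003 * (class_index - 1) +
                7919 * (iteration - 1)) %% 2147483647)
}

#' Generate synthetic records from a fitted KDE-KNN synthesizer
#'
#' Runs the iterative sample/validate/filter loop. Each iteration draws a
#' batch of candidates per class from that class's KDE, discards candidates
#' the KNN validator assigns to the wrong class (utility check, first), then
#' discards candidates whose distance to the closest real record falls
#' below `sigma_multiplier * sigma` (privacy check; strict: a candidate at
#' exactly the threshold is kept). Survivors accumulate until both per-class
#' targets are met, at which point the surplus is truncated in draw order.
#'
#' @param object A fitted [kdeknn()] model.
#' @param nsim Per-class targets: length-2 vector `(positive, negative)` or
#'   a single count applied to both classes. Default `c(540, 540)`, a
#'   balanced set.
#' @param seed Integer seed for the sampling streams; the caller's RNG
#'   state is untouched. `NULL` draws a base seed from the ambient stream.
#' @param batch_size Candidates drawn per class per iteration; default =
#'   that class's target.
#' @param max_iterations Iteration cap (default 100). Exhausting it raises
#'   a condition of class `kdeknn_nonconvergence` carrying the partial
#'   report in `$report`.
#' @param utility_validation,privacy_validation Toggle the two screens;
#'   with both off the output is exactly the raw per-class KDE draws.
#' @param sigma_multiplier Optional override of the fitted model's privacy
#'   multiplier for this run.
#' @param ... Unused.
#'
#' @return A standardized [tabular_dataset()] with exactly the requested
#'   number of records per class (positive rows first), with attribute
#'   `"report"`: a `generation_report` holding the sigma reference, the
#'   threshold, per-class bandwidths and per-class accounting (drawn =
#'   accepted + rejected_utility + rejected_privacy).
#' @export
simulate.kdeknn <- function(object, nsim = c(540, 540), seed = NULL, ...,
                            batch_size = NULL, max_iterations = 100,
                            utility_validation = TRUE,
                            privacy_validation = TRUE,
                            sigma_multiplier = NULL) {
  if (length(nsim) == 1L) nsim <- rep(nsim, 2L)
  if (length(nsim) != 2L || any(is.na(nsim)) || any(nsim < 0)) {
    stopf("nsim must be one or two non-negative counts")
  }
  target <- as.integer(nsim)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  seed <- as.integer(seed)
  if (!is.null(batch_size) &&
      (length(batch_size) != 1L || is.na(batch_size) || batch_size < 1L)) {
    stopf("batch_size must be a count >= 1")
  }
  if (max_iterations < 1L) stopf("max_iterations must be >= 1")
  mult <- if (is.null(sigma_multiplier)) object$sigma_multiplier
          else sigma_multiplier
  if (!(length(mult) == 1L && is.finite(mult) && mult >= 0)) {
    stopf("sigma_multiplier must be a non-negative scalar")
  }
  threshold <- mult * object$sigma

  kdes <- list(object$kde_pos, object$kde_neg)
  intended <- c(1L, 0L)
  train_values <- object$train$values
  pool <- list(matrix(numeric(0), 0L, length(object$feature_names)),
               matrix(numeric(0), 0L, length(object$feature_names)))
  drawn <- rej_util <- rej_priv <- accepted <- integer(2L)
  iterations <- 0L

  for (it in seq_len(max_iterations)) {
    progressed <- FALSE
    for (cls in 1:2) {
      if (nrow(pool[[cls]]) >= target[cls]) next
      progressed <- TRUE
      batch <- if (is.null(batch_size)) max(target[cls], 1L)
               else as.integer(batch_size)
      cand <- sample_kde(kdes[[cls]], batch,
                         seed = child_seed(seed, cls, it))
      drawn[cls] <- drawn[cls] + batch
      keep <- rep(TRUE, batch)
      if (utility_validation) {
        ok <- validate_candidates(object$knn, cand, intended[cls])
        rej_util[cls] <- rej_util[cls] + sum(!ok)
        keep <- ok
      }
      if (privacy_validation && any(keep)) {
        dcr <- dcr_synthetic(cand[keep, , drop = FALSE],
                             train_values)$distances
        ok <- dcr >= threshold
        rej_priv[cls] <- rej_priv[cls] + sum(!ok)
        keep[keep] <- ok
      }
      surv <- cand[keep, , drop = FALSE]
      accepted[cls] <- accepted[cls] + nrow(surv)
      pool[[cls]] <- rbind(pool[[cls]], surv)
    }
    iterations <- it
    if (!progressed ||
        (nrow(pool[[1L]]) >= target[1L] && nrow(pool[[2L]]) >= target[2L])) {
      break
    }
  }

  report <- structure(
    list(
      iterations = iterations,
      sigma = object$sigma,
      sigma_multiplier = mult,
      threshold = threshold,
      bandwidth = c(positive = object$kde_pos$h, negative = object$kde_neg$h),
      seed = seed,
      per_class = data.frame(
        class = c("positive", "negative"),
        target = target,
        drawn = drawn,
        rejected_utility = rej_util,
        rejected_privacy = rej_priv,
        accepted = accepted
      )
    ),
    class = "generation_report"
  )

  if (nrow(pool[[1L]]) < target[1L] || nrow(pool[[2L]]) < target[2L]) {
    cond <- structure(
      class = c("kdeknn_nonconvergence", "error", "condition"),
      list(
        message = sprintf(
          paste0("generation did not converge in %d iterations ",
                 "(accepted %d/%d positive, %d/%d negative); ",
                 "consider relaxing sigma_multiplier or the bandwidth"),
          iterations, nrow(pool[[1L]]), target[1L],
          nrow(pool[[2L]]), target[2L]),
        call = sys.call(-1L),
        report = report
      )
    )
    stop(cond)
  }

  values <- rbind(pool[[1L]][seq_len(target[1L]), , drop = FALSE],
                  pool[[2L]][seq_len(target[2L]), , drop = FALSE])
  colnames(values) <- object$feature_names
  out <- tabular_dataset(values,
                         labels = rep(intended, target),
                         feature_names = object$feature_names,
                         label_name = object$train$label_name)
  attr(out, "report") <- report
  out
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf("generation_report: %d iteration(s), seed %d\n",
              x$iterations, x$seed))
  cat(sprintf("  sigma = %.4f, multiplier = %g, threshold = %.4f\n",
              x$sigma, x$sigma_multiplier, x$threshold))
  cat(sprintf("  bandwidth: %.4f (pos), %.4f (neg)\n",
              x$bandwidth["positive"], x$bandwidth["negative"]))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Export synthetic records on the original clinical scale
#'
#' Inverse-standardizes a standardized synthetic dataset with the training
#' preprocessor and writes it as CSV (label column last).
#'
#' @param synthetic Standardized [tabular_dataset()] (e.g. from
#'   [simulate.kdeknn()]).
#' @param preprocess The fitted [fit_preprocessor()] model of the training
#'   data.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_synthetic <- function(synthetic, preprocess, path) {
  write_csv_dataset(invert_preprocessor(preprocess, synthetic), path)
}
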