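# A well-separated two-cluster training set: utility misclassification is
# effectively measure-zero, so generation behaviour is predictable.
separated_train <- function(n0 = 40, n1 = 40, d = 2, gap = 20, seed = 2) {
  withr::with_seed(seed, {
    vals <- rbind(matrix(rnorm(n0 * d), n0, d),
                  matrix(rnorm(n1 * d) + gap, n1, d))
    tabular_dataset(vals, labels = rep(c(0L, 1L), c(n0, n1)))
  })
}

test_that("class partition conserves rows and respects labels", {
  ds <- tabular_dataset(rand_matrix(3, 2), labels = c(1, 0, 1))
  parts <- partition_by_class(ds)
  expect_equal(nrow(parts$positive$values), 2)
  expect_equal(nrow(parts$negative$values), 1)
  key <- function(m) sort(apply(m, 1, paste, collapse = "|"))
  expect_identical(key(rbind(parts$positive$values, parts$negative$values)),
                   key(ds$values))
  one <- tabular_dataset(rand_matrix(3, 2), labels = c(1, 1, 1))
  expect_error(partition_by_class(one), "both classes")
})

test_that("default fixture imbalance carries into the stratified split", {
  ds <- make_clinical_fixture(seed = 12)
  sp <- split_train_test(ds, 0.15, seed = 1)
  frac <- mean(sp$train$labels == 1L)
  expect_equal(frac, 296 / 1275, tolerance = 0.01)
})

test_that("separated clusters with no privacy filter converge in one pass", {
  train <- separated_train()
  fit <- kdeknn(train, k = 5, sigma_multiplier = 0)
  syn <- simulate(fit, nsim = c(50, 50), seed = 3)
  rep <- attr(syn, "report")
  expect_equal(rep$iterations, 1)
  expect_equal(rep$per_class$rejected_utility, c(0, 0))
  expect_equal(rep$per_class$rejected_privacy, c(0, 0))
  expect_equal(c(sum(syn$labels == 1L), sum(syn$labels == 0L)),
               c(50L, 50L))
})

test_that("an unattainable privacy threshold raises a typed error with report", {
  train <- separated_train(n0 = 20, n1 = 20)
  fit <- kdeknn(train, sigma_multiplier = 1)
  # threshold far beyond the support diameter + kernel reach
  diam <- max(dist(train$values))
  mult <- (diam + 10 * max(fit$kde_pos$h, fit$kde_neg$h)) / fit$sigma
  err <- tryCatch(
    simulate(fit, nsim = c(10, 10), seed = 5, max_iterations = 3,
             sigma_multiplier = mult),
    kdeknn_nonconvergence = function(e) e
  )
  expect_s3_class(err, "kdeknn_nonconvergence")
  expect_s3_class(err$report, "generation_report")
  expect_equal(err$report$per_class$accepted, c(0, 0))
  expect_equal(err$report$iterations, 3)
})

test_that("with both validations off the output is raw per-class KDE draws", {
  train <- make_std_train(n0 = 50, n1 = 25, d = 3, effect = 1, seed = 9)
  fit <- kdeknn(train)
  syn <- simulate(fit, nsim = c(30, 40), seed = 11,
                  utility_validation = FALSE, privacy_validation = FALSE)
  raw_pos <- sample_kde(fit$kde_pos, 30, seed = kdeknn:::child_seed(11, 1, 1))
  raw_neg <- sample_kde(fit$kde_neg, 40, seed = kdeknn:::child_seed(11, 2, 1))
  expect_identical(unname(syn$values[1:30, ]), unname(raw_pos))
  expect_identical(unname(syn$values[31:70, ]), unname(raw_neg))
})

test_that("generation is deterministic and satisfies its invariants", {
  train <- make_std_train(n0 = 120, n1 = 60, d = 4, effect = 2, seed = 13)
  fit <- kdeknn(train, k = 5, sigma_multiplier = 1)
  syn1 <- simulate(fit, nsim = c(80, 80), seed = 17)
  syn2 <- simulate(fit, nsim = c(80, 80), seed = 17)
  expect_identical(syn1$values, syn2$values)
  expect_identical(attr(syn1, "report")$per_class,
                   attr(syn2, "report")$per_class)

  rep <- attr(syn1, "report")
  # accounting conservation
  expect_equal(rep$per_class$drawn,
               rep$per_class$accepted + rep$per_class$rejected_utility +
                 rep$per_class$rejected_privacy)
  # exact class balance at the configured targets
  expect_equal(sum(syn1$labels == 1L), 80)
  expect_equal(sum(syn1$labels == 0L), 80)
  # post-hoc utility invariant: every record classifies as intended
  expect_identical(predict(fit$knn, syn1$values), syn1$labels)
  # post-hoc privacy floor
  expect_gte(min(dcr_synthetic(syn1$values, train$values)$distances),
             rep$threshold)
})

test_that("acceptance rate is non-increasing in the privacy multiplier", {
  train <- make_std_train(n0 = 100, n1 = 50, d = 3, effect = 2, seed = 19)
  fit <- kdeknn(train)
  # one iteration with a fixed seed: every multiplier screens the exact
  # same candidate batch, so monotonicity must hold deterministically
  rates <- vapply(c(0, 0.5, 1, 2), function(mult) {
    rep <- tryCatch({
      syn <- simulate(fit, nsim = c(500, 500), seed = 23,
                      sigma_multiplier = mult, max_iterations = 1)
      attr(syn, "report")
    }, kdeknn_nonconvergence = function(e) e$report)
    sum(rep$per_class$accepted) / sum(rep$per_class$drawn)
  }, numeric(1))
  expect_true(all(diff(rates) <= 1e-12))
})

test_that("unvalidated synthetic class means recover the support means", {
  train <- make_std_train(n0 = 150, n1 = 100, d = 3, effect = 1.5, seed = 29)
  fit <- kdeknn(train)
  syn <- simulate(fit, nsim = c(2000, 2000), seed = 31,
                  utility_validation = FALSE, privacy_validation = FALSE)
  parts <- partition_by_class(train)
  for (cls in c("positive", "negative")) {
    support <- parts[[cls]]$values
    lab <- if (cls == "positive") 1L else 0L
    sm <- colMeans(syn$values[syn$labels == lab, , drop = FALSE])
    h <- if (cls == "positive") fit$kde_pos$h else fit$kde_neg$h
    se <- sqrt((apply(support, 2, var) + h^2) / 2000)
    expect_true(all(abs(sm - colMeans(support)) < 3.5 * se))
  }
})

test_that("synthetic export round-trips through the original scale", {
  ds <- make_clinical_fixture(n_control = 60, n_case = 30, d = 3,
                              missing_rate = 0.05, seed = 37)
  prep <- fit_preprocessor(ds)
  train <- apply_preprocessor(prep, ds)
  fit <- kdeknn(train, sigma_multiplier = 0)
  syn <- simulate(fit, nsim = c(20, 20), seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  export_synthetic(syn, prep, path)
  back <- read_csv_dataset(path, "label", positive_label = 1)
  expect_equal(sum(back$labels == 1L), 20)
  restd <- apply_preprocessor(prep, back)
  expect_equal(restd$values, syn$values, tolerance = 1e-10)
})
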