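test_that("KS battery matches hand-stepped empirical CDFs", {
  real <- cbind(a = c(1, 2, 3, 4))
  syn <- cbind(a = c(1.5, 2.5, 3.5, 4.5))
  out <- ks_battery(real, syn)
  expect_equal(out$table$statistic, 0.25)

  # identical columns: statistic 0, p-value 1
  same <- ks_battery(real, real)
  expect_equal(same$table$statistic, 0)
  expect_equal(same$table$p_value, 1)

  # disjoint supports: statistic 1
  set.seed(111)
  r <- cbind(x = runif(50))
  s <- cbind(x = runif(50) + 10)
  expect_equal(ks_battery(r, s)$table$statistic, 1)
})

test_that("KS mean p-value averages the per-feature battery", {
  set.seed(121)
  real <- rand_matrix(80, 4)
  syn <- rand_matrix(60, 4)
  out <- ks_battery(real, syn)
  expect_equal(out$mean_p_value, mean(out$table$p_value))
  expect_equal(nrow(out$table), 4)
})

test_that("density and coverage match hand cases", {
  # real {0, 2}, k = 1 (r = 2 for both), synthetic {1}:
  # density = 2 (not upper bounded by 1), coverage = 1
  dc <- density_coverage(matrix(c(0, 2)), matrix(1), k = 1)
  expect_equal(dc$density, 2)
  expect_equal(dc$coverage, 1)

  # synthetic = real (distinct points): each real covered by its copy
  set.seed(131)
  X <- rand_matrix(30, 3)
  expect_equal(density_coverage(X, X, k = 5)$coverage, 1)

  # synthetic beyond every ball: both metrics zero
  far <- rand_matrix(10, 3) + 100
  dc0 <- density_coverage(X, far, k = 5)
  expect_equal(dc0$density, 0)
  expect_equal(dc0$coverage, 0)

  expect_error(density_coverage(rand_matrix(4, 2), rand_matrix(3, 2), k = 5),
               "more real points")
})

test_that("density/coverage agree with the brute-force double loop", {
  set.seed(141)
  for (rep in 1:8) {
    n <- sample(20:120, 1)
    q <- sample(10:120, 1)
    d <- sample(1:5, 1)
    X <- rand_matrix(n, d)
    S <- rand_matrix(q, d) * 1.5
    got <- density_coverage(X, S, k = 5)
    want <- oracle_density_coverage(X, S, k = 5)
    expect_equal(got$density, want$density)
    expect_equal(got$coverage, want$coverage)
  }
})

test_that("density and coverage are translation invariant", {
  set.seed(151)
  X <- rand_matrix(40, 3)
  S <- rand_matrix(30, 3)
  shift <- rep(7.5, 3)
  a <- density_coverage(X, S, k = 5)
  b <- density_coverage(sweep(X, 2, shift, "+"), sweep(S, 2, shift, "+"),
                        k = 5)
  expect_equal(a$density, b$density)
  expect_equal(a$coverage, b$coverage)
})

test_that("moment comparison reports sample moments with 95% CIs", {
  real <- cbind(f = c(1, 2, 3))
  out <- moment_comparison(real, real)
  expect_equal(out$real_mean, 2)
  expect_equal(out$real_var, 1)
  expect_equal(out$syn_mean, out$real_mean)
  expect_equal(out$syn_ci_lower, out$real_ci_lower)

  # CI half-width 1.96 * s / sqrt(n): n = 100, s = 1 -> 0.196
  x <- as.numeric(scale(rnorm(100))) # exact unit sample sd
  m <- moment_comparison(cbind(x), cbind(x))
  expect_equal(m$real_ci_upper - m$real_mean, 0.196)
})

test_that("shift report follows the Mann-Whitney min-U convention", {
  a <- cbind(f = c(1, 2, 3))
  b <- cbind(f = c(10, 11, 12))
  out <- shift_report(a, b)
  expect_equal(out$U, 0) # all 9 pairs discordant

  # identical cohorts: U = n1*n2/2 and nothing significant
  same <- shift_report(a, a)
  expect_equal(same$U, 9 / 2)
  expect_false(any(same$significant))
})

test_that("Bonferroni adjustment is capped, monotone, and drives the flag", {
  set.seed(161)
  a <- rand_matrix(40, 6)
  b <- rand_matrix(40, 6)
  b[, 2] <- b[, 2] + 5 # one genuinely shifted feature
  out <- shift_report(a, b)
  expect_equal(out$p_adjusted, pmin(1, 6 * out$p_value))
  expect_true(all(out$p_adjusted <= 1))
  expect_true(all(diff(out$p_adjusted[order(out$p_value)]) >= 0))
  expect_identical(out$significant, out$p_adjusted < 0.01)
  expect_true(out$significant[2])
  expect_false(any(out$significant[-2]))
})

test_that("strongly shifted features are flagged with high power", {
  pair <- make_shifted_pair(shift = c(rep(2, 5), rep(0, 15)),
                            n_control = 150, n_case = 50, d = 20,
                            effect = 0, missing_rate = 0.02, seed = 171)
  out <- shift_report(pair$a, pair$b)
  expect_true(all(out$significant[1:5]))
  expect_lt(sum(out$significant[6:20]), 3)
})

test_that("audit_synthetic bundles the metric suite consistently", {
  set.seed(181)
  X <- rand_matrix(60, 3)
  S <- rand_matrix(50, 3)
  rep <- audit_synthetic(X, S, k = 5)
  expect_equal(rep$dcr_real$mean, dcr_real_real(X)$mean)
  expect_equal(rep$dcr_synthetic$mean, dcr_synthetic(S, X)$mean)
  dc <- density_coverage(X, S, k = 5)
  expect_equal(rep$density, dc$density)
  expect_equal(rep$coverage, dc$coverage)
  expect_equal(nrow(rep$moments), 3)
})
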