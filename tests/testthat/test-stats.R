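# Brute-force Lilliefors statistic: max empirical-CDF gap against the
# normal fitted to the sample, enumerating both one-sided candidates at
# every sample point.
lilliefors_oracle <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  gaps <- numeric(0)
  for (i in seq_len(n)) {
    gaps <- c(gaps, abs(i / n - pnorm(z[i])), abs(pnorm(z[i]) - (i - 1) / n))
  }
  max(gaps)
}

test_that("the lilliefors statistic equals the brute-force CDF gap", {
  expect_equal(hospwait:::lilliefors_statistic(c(-1, 0, 1)),
               lilliefors_oracle(c(-1, 0, 1)))
  set.seed(14)
  for (rep in 1:10) {
    x <- rnorm(sample(5:60, 1), sample(-5:5, 1), runif(1, 0.5, 4))
    expect_equal(hospwait:::lilliefors_statistic(x), lilliefors_oracle(x))
  }
})

test_that("the lilliefors statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(15)
  for (rep in 1:5) {
    x <- rgamma(50, shape = 2)
    expect_equal(hospwait:::lilliefors_statistic(x),
                 unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
  }
})

test_that("monte-carlo lilliefors p-values separate normal from skewed data", {
  set.seed(16)
  p_norm <- vapply(1:10, function(s) {
    lilliefors_test(rnorm(500), n_montecarlo = 300)$p_value
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_exp <- vapply(1:10, function(s) {
    lilliefors_test(rexp(500), n_montecarlo = 300)$p_value
  }, numeric(1))
  expect_equal(mean(p_exp < 0.05), 1)
  expect_error(lilliefors_test(c(1, 2, 3)), "n >= 4")
  expect_error(lilliefors_test(rep(2, 10)), "zero variance")
})

test_that("KL divergence is zero for identical samples, positive otherwise", {
  set.seed(17)
  x <- rnorm(500)
  expect_equal(kl_divergence(x, x), 0)
  y <- rnorm(500, 1.5)
  d_xy <- kl_divergence(x, y)
  d_yx <- kl_divergence(y, x)
  expect_gt(d_xy, 0)
  expect_false(isTRUE(all.equal(d_xy, d_yx)))   # asymmetric in general
  expect_error(kl_divergence(x, y, n_bins = 1), "n_bins")
  expect_error(kl_divergence(numeric(0), y), "non-empty")
  # nonnegativity across random pairs
  for (rep in 1:10) {
    a <- rgamma(200, runif(1, 0.5, 3))
    b <- rgamma(200, runif(1, 0.5, 3))
    expect_gte(kl_divergence(a, b), 0)
  }
})

test_that("pre-binned KL matches hand arithmetic", {
  expect_equal(kl_from_probs(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(round(kl_from_probs(c(0.5, 0.5), c(0.25, 0.75)), 4), 0.1438)
  expect_equal(kl_from_probs(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_error(kl_from_probs(c(1, 0), c(0, 1)), "positive wherever")
})

test_that("gini matches the pairwise-difference definition", {
  gini_oracle <- function(x) {
    sum(abs(outer(x, x, `-`))) / (2 * length(x)^2 * mean(x))
  }
  expect_equal(gini(c(3, 3, 3)), 0)
  expect_equal(gini(c(0, 1)), 0.5)
  expect_equal(gini(c(1, 2, 3)), 2 / 9)
  set.seed(18)
  for (rep in 1:10) {
    x <- rgamma(30, 2)
    expect_equal(gini(x), gini_oracle(x), tolerance = 1e-12)
    expect_equal(gini(7.3 * x), gini(x), tolerance = 1e-12)  # scale-invariant
  }
  expect_error(gini(c(0, 0, 0)), "degenerate")
  expect_error(gini(5), "n >= 2")
  expect_error(gini(c(-1, 2)), "nonnegative")
})

test_that("flow error averages element-wise share discrepancies", {
  a <- matrix(c(60, 40, 30, 70), 2, 2, byrow = TRUE)
  expect_equal(flow_error(a, a), c(mean = 0, sd = 0))
  b <- matrix(c(64, 36, 30, 70), 2, 2, byrow = TRUE)
  expect_equal(flow_error(b, a)[["mean"]], 2.0)
  # permuting both matrices' rows identically changes nothing
  expect_equal(flow_error(b[2:1, ], a[2:1, ]), flow_error(b, a))
  expect_error(flow_error(a, a[1, , drop = FALSE]), "identical shape")
  expect_error(flow_error(matrix(c(50, 30, 30, 70), 2, 2), a), "sum to 100")
})

test_that("distribution summaries report moments and normality", {
  set.seed(19)
  s <- distribution_summary(rnorm(300, 2, 0.5), n_montecarlo = 200)
  expect_equal(s$mean, 2, tolerance = 0.1)
  expect_equal(s$sd, 0.5, tolerance = 0.1)
  expect_gt(s$lilliefors_p, 0.05)
  expect_equal(s$n, 300L)
})
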