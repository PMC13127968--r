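test_that("notched priors renormalize to unit mass", {
  for (fam in c("half_cauchy", "full_cauchy")) {
    pr <- notched_prior(fam)
    mass <- integrate(function(d) notched_prior_density(pr, d),
                      -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-6)
    expect_equal(notched_prior_density(pr, 0.25), 0)  # inside the notch
  }
  expect_equal(notched_prior_density(notched_prior("half_cauchy"), -1), 0)
  expect_gt(notched_prior_density(notched_prior("full_cauchy"), -1), 0)
})

test_that("the directional Bayes factor is strictly increasing in t", {
  pr <- notched_prior("half_cauchy")
  bfs <- vapply(seq(-2, 6, by = 0.5), notched_bf_t, numeric(1), n = 16,
                prior = pr)
  expect_true(all(diff(bfs) > 0))
  # data at the null cannot favour a d > 0.5 alternative
  expect_lt(notched_bf_t(0, 16, pr), 1)
  # negative effects are evidence against a directional alternative
  expect_lt(notched_bf_t(-2, 16, pr), notched_bf_t(0, 16, pr))
})

test_that("shrinking the notch recovers the un-notched directional Cauchy BF", {
  t <- 2.5; n <- 16
  plain <- notched_bf_t(t, n, notched_prior("half_cauchy", notch = 0))
  shrunk <- notched_bf_t(t, n, notched_prior("half_cauchy", notch = 1e-7))
  expect_equal(shrunk, plain, tolerance = 1e-5)
})

test_that("the two-sided prior is symmetric under sign flips", {
  pr <- notched_prior("full_cauchy")
  withr::with_seed(3, v <- rnorm(12, 0.4, 0.5))
  expect_equal(notched_bf(v, 0, pr), notched_bf(-v, 0, pr), tolerance = 1e-8)
})

test_that("degenerate group inputs raise informative errors", {
  expect_error(notched_bf(rep(0.3, 10)),
               class = "rotadecode_error_zero_variance")
  expect_error(notched_bf(c(0.1, 0.2)), ">= 3")
  g <- matrix(rnorm(5 * 4), 5, 4)
  # identical conditions give all-zero differences: zero-variance, located
  expect_error(difference_bf_timecourse(g, g),
               class = "rotadecode_error_zero_variance")
  expect_error(difference_bf_timecourse(g, g[, 1:3]), "same subjects")
})

test_that("BF time-courses classify evidence and support latency extraction", {
  # effect present from 100 ms on, absent before
  times <- seq(-20, 200, by = 20)
  withr::with_seed(5, {
    g <- vapply(times, function(t) {
      rnorm(16, mean = if (t >= 100) 0.25 else 0, sd = 0.15)
    }, numeric(16))
  })
  bf <- bf_timecourse(g, null_value = 0, times_ms = times)
  expect_s3_class(bf, "bayes_result")
  expect_equal(nrow(bf), length(times))
  expect_true(all(bf$bf10 > 0))
  expect_true(all(bf$evidence[bf$bf10 > 10] == "supports_alt"))
  ls <- latency_summary(bf, colMeans(g))
  expect_equal(ls$onset_ms, min(bf$time_ms[bf$time_ms >= 100 & bf$bf10 > 10]))
  expect_true(ls$peak_ms >= 100)

  # single-column input works
  bf1 <- bf_timecourse(g[, 1, drop = FALSE], times_ms = times[1])
  expect_equal(nrow(bf1), 1)

  # no crossing, monotone mean: peak at the maximum, onset absent
  flat <- bf_timecourse(matrix(rnorm(48, 0, 1), 16, 3), times_ms = c(10, 20, 30))
  mean3 <- c(0.1, 0.3, 0.2)
  ls2 <- latency_summary(flat, mean3)
  expect_equal(ls2$peak_ms, 20)
  expect_true(is.na(ls2$onset_ms) || ls2$onset_ms > 0)
})

test_that("a null cohort almost never yields strong-alternative evidence", {
  n_alt <- 0; n_total <- 0
  for (s in 1:10) {
    withr::with_seed(600 + s, g <- matrix(rnorm(16 * 20), 16, 20))
    bf <- bf_timecourse(g, null_value = 0, times_ms = seq_len(20))
    n_alt <- n_alt + sum(bf$evidence == "supports_alt")
    n_total <- n_total + nrow(bf)
  }
  expect_lt(n_alt / n_total, 0.01)
})

test_that("bootstrap bands are reproducible, degenerate-safe and calibrated", {
  g <- matrix(rep(0.3, 8 * 4), 8, 4)
  ci <- bootstrap_ci(g, n_boot = 100, seed = 1)
  expect_equal(ci$ci_lo, ci$ci_hi)
  expect_equal(ci$mean, rep(0.3, 4))

  withr::with_seed(9, h <- matrix(rnorm(8 * 6), 8, 6))
  expect_identical(bootstrap_ci(h, n_boot = 500, seed = 4),
                   bootstrap_ci(h, n_boot = 500, seed = 4))
  expect_false(identical(bootstrap_ci(h, n_boot = 500, seed = 4)$ci_lo,
                         bootstrap_ci(h, n_boot = 500, seed = 5)$ci_lo))

  # coverage of the true mean across simulated cohorts; the percentile
  # bootstrap is first-order accurate, so modest undercoverage at finite
  # cohort sizes is expected and the band reflects that
  withr::with_seed(10, {
    cover <- 0
    for (i in 1:300) {
      cohort <- matrix(rnorm(25, mean = 0.4, sd = 0.3), 25, 1)
      ci <- bootstrap_ci(cohort, n_boot = 300, seed = i)
      cover <- cover + (ci$ci_lo <= 0.4 && 0.4 <= ci$ci_hi)
    }
  })
  expect_gt(cover / 300, 0.89)
  expect_lt(cover / 300, 0.99)
})
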