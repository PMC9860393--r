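test_that("rate and ISI CV follow their definitions", {
  rc <- rate_and_cv(c(1, 2, 3, 4), 10)
  expect_equal(rc$rate, 0.4)
  expect_equal(rc$isi_cv, 0)

  # exponential ISIs: CV -> 1
  set.seed(3)
  times <- cumsum(rexp(1e4, 0.148))
  rc2 <- rate_and_cv(times, max(times))
  expect_lt(abs(rc2$isi_cv - 1), 3 / sqrt(1e4))

  # scale invariance under time dilation
  expect_equal(rate_and_cv(times * 7, max(times) * 7)$isi_cv, rc2$isi_cv)

  expect_true(is.na(rate_and_cv(c(1, 2), 10)$isi_cv))
  expect_error(rate_and_cv(c(3, 2, 1), 10), "increasing")
  expect_error(rate_and_cv(c(1, 2), 0), "duration")
})

test_that("the Jarque-Bera statistic matches a brute-force moment oracle", {
  x <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  expect_lt(abs(jarque_bera(x) - jb_bruteforce(x)), 1e-12)

  set.seed(8)
  for (k in 1:10) {
    y <- rlnorm(50)
    expect_lt(abs(jarque_bera(y) - jb_bruteforce(y)), 1e-10)
  }

  # symmetric mesokurtic sample: JB near zero
  q <- qnorm(ppoints(200))
  expect_lt(jarque_bera(q), 0.5)

  expect_error(jarque_bera(rep(1, 20)), "variance")
  expect_error(jarque_bera(c(1, 2)), "n >= 8")
})

test_that("Monte-Carlo critical values approach the asymptotic chi-squared law", {
  # large n: critical value near qchisq(0.95, 2) = 5.99
  cv <- jb_critical_value(2000, replicates = 1e4, seed = 13)
  expect_lt(abs(cv - qchisq(0.95, 2)), 0.6)

  # determinism of the cache and of the simulation
  a <- jb_critical_value(37, replicates = 5000, seed = 2)
  b <- jb_critical_value(37, replicates = 5000, seed = 2)
  expect_identical(a, b)

  # small-n critical values sit well below the asymptotic one
  cv20 <- jb_critical_value(20, replicates = 2e4, seed = 3)
  expect_lt(cv20, qchisq(0.95, 2))
  expect_gt(cv20, 0)
})

test_that("multimodality flag is calibrated under the null and fires on mixtures", {
  null <- jb_null_table(50, replicates = 2e4, seed = 4)

  # calibration: ~5% rejections for normal samples
  set.seed(5)
  rej <- mean(vapply(1:400, function(i)
    as.logical(multimodality_flag(rnorm(50), null)), TRUE))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400))

  # balanced two-point mixture: flagged
  mix <- rep(c(0.3, 1.5), 25)
  expect_true(as.logical(multimodality_flag(mix, null)))

  # too-small samples are indeterminate
  expect_true(is.na(multimodality_flag(c(1, 2, 3))))
  expect_error(multimodality_flag(rnorm(60), null), "cover")
})

test_that("amplitude normalization preserves within-cell structure", {
  cells <- list(
    list(control = c(1, 2, 3), treated = c(0.5, 1)),
    list(control = c(10, 20), treated = c(5)))
  pooled <- normalize_amplitudes(cells)
  # per-cell control mean is exactly 1 after normalization
  expect_equal(mean(pooled$control[1:3]), 1)
  expect_equal(mean(pooled$control[4:5]), 1)
  # within-cell ratios unchanged
  expect_equal(pooled$treated[3] / pooled$control[4], 5 / 10)

  expect_warning(
    normalize_amplitudes(list(list(control = numeric(0), treated = 1:3),
                              cells[[1]])),
    "excluded")
})

test_that("paired regression recovers exact and affine-invariant fits", {
  x <- c(1, 2, 3, 4, 5)
  reg <- paired_regression(x, 2 * x)
  expect_equal(reg$slope, 2)
  expect_equal(reg$r_squared, 1)

  set.seed(6)
  xs <- rnorm(100); ys <- xs + rnorm(100)
  r1 <- paired_regression(xs, ys)$r_squared
  r2 <- paired_regression(10 * xs + 3, -2 * ys + 7)$r_squared
  expect_equal(r1, r2, tolerance = 1e-12)

  expect_error(paired_regression(1:5, rep(2, 5)), "variance")
  expect_error(paired_regression(1:5, 1:4), "matched")
})

test_that("activity index is the amplitude-sum rate", {
  x <- trace(rnorm(6000, 0, 0.01), 60)   # 100 s
  expect_identical(activity_index(x, numeric(0)), 0)
  expect_equal(activity_index(x, rep(1, 10)), 0.1)
  # alternative derivative mode exists and is non-negative
  expect_gte(activity_index(x, rep(1, 10), mode = "positive_derivative"), 0)
})

test_that("condition comparisons dispatch the right paired and pooled tests", {
  pre <- c(1, 2, 3, 4, 5, 6)
  same <- compare_conditions(pre, pre, "paired")
  expect_equal(same$p_value, 1)

  shifted <- compare_conditions(pre, pre + 5, "paired")
  expect_lt(shifted$p_value, 0.05)

  set.seed(7)
  ks <- compare_conditions(rnorm(300), rnorm(300, 2), "distribution")
  expect_lt(ks$p_value, 1e-6)

  expect_error(compare_conditions(1:6, 1:5, "paired"), "matched")
  expect_error(compare_conditions(1:3, 1:3, "paired"), ">= 5")
})
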