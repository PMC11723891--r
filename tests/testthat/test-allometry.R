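test_that("MA slope through the origin matches exact and brute-force cases", {
  u <- c(1, 2, 3, -1, 0.5)
  expect_equal(ma_slope_through_origin(u, u)$beta, 1)
  expect_equal(ma_slope_through_origin(u, u)$r2, 1)
  expect_equal(ma_slope_through_origin(u, 2 * u)$beta, 2)

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(8:40, 1)
    x <- rnorm(n)
    y <- runif(1, 0.3, 3) * x + rnorm(n, sd = 0.5)
    fit <- ma_slope_through_origin(x, y)
    expect_equal(fit$beta, ma_brute(x, y), tolerance = 1e-6)
  }
  expect_error(ma_slope_through_origin(rep(0, 5), rep(0, 5)), "zero")
})

test_that("MA slope is scale-invariant and reciprocal under axis swap", {
  set.seed(77)
  u <- rnorm(16); v <- 1.4 * u + rnorm(16, sd = 0.3)
  f1 <- ma_slope_through_origin(u, v)
  f2 <- ma_slope_through_origin(3.7 * u, 3.7 * v)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
  # perpendicular distances are symmetric in the two axes, so swapping
  # them inverts the slope exactly (hence the product dominates r^4)
  swn <- ma_slope_through_origin(v, u)
  expect_equal(f1$beta * swn$beta, 1, tolerance = 1e-12)
  expect_gte(f1$beta * swn$beta, f1$r2^2 - 1e-12)
})

test_that("slope test is null on the true line and powered on slope 2", {
  u <- c(1, 2, 3, 4)
  exact <- ma_slope_test(u, u, b0 = 1)
  expect_true(exact$exact_fit)
  expect_equal(exact$p, 1)
  expect_equal(exact$wald_r, 0)

  set.seed(5)
  u <- rnorm(50); v <- 2 * u + rnorm(50, sd = 0.1)
  expect_lt(ma_slope_test(u, v, b0 = 1)$p, 0.001)
  # testing at the fitted slope itself gives r_w = 0
  b <- ma_slope_through_origin(u, v)$beta
  expect_equal(ma_slope_test(u, v, b0 = b)$wald_r, 0, tolerance = 1e-10)
})

test_that("confidence interval brackets the estimate and is test-dual", {
  set.seed(9)
  u <- rnorm(16); v <- 1.5 * u + rnorm(16, sd = 0.4)
  fit <- ma_slope_through_origin(u, v)
  ci <- ma_confidence_interval(u, v)
  expect_lt(ci$lcl, fit$beta)
  expect_gt(ci$ucl, fit$beta)
  # interval width shrinks to zero as noise vanishes
  ci_tight <- ma_confidence_interval(u, 1.5 * u + rnorm(16, sd = 1e-4))
  expect_lt(ci_tight$ucl - ci_tight$lcl, 1e-3)

  # duality: p < alpha iff b0 is outside the interval
  for (seed in 1:100) {
    set.seed(seed)
    x <- rnorm(12); y <- runif(1, 0.5, 2) * x + rnorm(12, sd = 0.6)
    ci <- ma_confidence_interval(x, y)
    if (ci$unbounded) next
    for (b0 in c(0.5, 1, 2)) {
      p <- ma_slope_test(x, y, b0)$p
      outside <- b0 < ci$lcl || b0 > ci$ucl
      expect_equal(p < 0.05, outside,
                   info = sprintf("seed %d b0 %.1f", seed, b0))
    }
  }
})

test_that("MA interval has near-nominal coverage", {
  set.seed(123)
  hits <- 0L; n_rep <- 1000L
  for (i in seq_len(n_rep)) {
    # equal error variance on both axes: the regime where the major axis
    # is the consistent estimate of the underlying line
    xi <- rnorm(16)
    x <- xi + rnorm(16, sd = 0.3)
    y <- 1.5 * xi + rnorm(16, sd = 0.3)
    ci <- ma_confidence_interval(x, y)
    if (!ci$unbounded && ci$lcl <= 1.5 && 1.5 <= ci$ucl) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.92)
  expect_lte(hits / n_rep, 0.98)
})

test_that("studentized outlier filter removes planted outliers only", {
  set.seed(31)
  keep_all <- 0L
  for (i in 1:200) {
    u <- rnorm(16); v <- u + rnorm(16, sd = 0.3)
    f <- studentized_outlier_filter(u, v)
    if (length(f$removed) == 0L) keep_all <- keep_all + 1L
  }
  expect_gte(keep_all / 200, 0.9)  # clean data rarely loses points

  set.seed(32)
  u <- rnorm(16); v <- u + rnorm(16, sd = 0.2)
  v[7] <- v[7] + 10 * 0.2  # displaced by 10 residual SDs
  f <- studentized_outlier_filter(u, v)
  expect_equal(f$removed, 7L)
  expect_equal(studentized_outlier_filter(u, v, threshold = Inf)$removed,
               integer(0))
})

test_that("positivization flips pairs jointly and leaves the MA slope alone", {
  expect_equal(positivize(-1, -2), list(u = 1, v = 2))
  expect_equal(positivize(1, -2), list(u = 1, v = -2))
  set.seed(8)
  u <- rnorm(20); v <- 1.3 * u + rnorm(20, sd = 0.4)
  p <- positivize(u, v)
  expect_true(all(p$u >= 0))
  expect_equal(ma_slope_through_origin(p$u, p$v)$beta,
               ma_slope_through_origin(u, v)$beta, tolerance = 1e-12)
})

test_that("degenerate (uncorrelated) contrast sets are flagged, not dropped", {
  u <- c(1, -1, 1, -1)
  v <- c(1, 1, -1, -1)  # Suv = 0: independent evolution
  fit <- ma_slope_through_origin(u, v)
  expect_true(fit$degenerate)
  expect_equal(fit$r2, 0)
  res <- ma_analysis(c(1, -1, 2, -2), c(1, 1, -1, -1), filter_threshold = Inf)
  expect_true(is.na(res$lcl) || res$degenerate)
})
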