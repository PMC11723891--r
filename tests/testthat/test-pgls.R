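test_that("GLS reduces to OLS under identity covariance", {
  set.seed(1)
  n <- 20
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "a", "b")
  y <- 1 + 2 * X[, 2] - X[, 3] + rnorm(n)
  fit <- gls_fit(X, y, diag(n))
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(fit$sigma2, summary(ols)$sigma^2, tolerance = 1e-10)
})

test_that("GLS coefficients match the explicit-inverse oracle", {
  for (seed in 1:20) {
    tr <- random_tree(10, seed = 200 + seed)
    V <- phylo_covariance(tr)
    set.seed(seed)
    X <- cbind(1, rnorm(10), rnorm(10))
    y <- rnorm(10)
    fit <- gls_fit(X, y, V)
    expect_equal(unname(fit$coefficients), c(gls_brute(X, y, V)),
                 tolerance = 1e-8)
  }
})

test_that("an exactly linear response gives zero residual variance", {
  tr <- random_tree(8, seed = 3)
  V <- phylo_covariance(tr)
  set.seed(3)
  X <- cbind(1, rnorm(8))
  y <- 2 + 3 * X[, 2]
  fit <- gls_fit(X, y, V)
  expect_equal(fit$rss_gls, 0, tolerance = 1e-18)
  expect_error(gls_fit(cbind(X, X[, 2]), y, V), "rank-deficient")
})

test_that("lambda profile optimum is consistent and bounded", {
  tr <- random_tree(30, seed = 8)
  V <- phylo_covariance(tr)
  set.seed(8)
  y <- sim_bm_trait(tr, lambda = 0.7, sigma2 = 1)
  x <- rnorm(30)
  X <- cbind(1, x)
  est <- estimate_lambda(X, y, V)
  expect_gte(est$lambda, 0)
  expect_lte(est$lambda, 1)
  # optimum dominates the whole grid and both endpoints
  expect_gte(est$loglik + 1e-6, max(est$profile$loglik))
  ll_at <- function(l) gls_fit(X, y, lambda_transform(V, l))$loglik
  expect_gte(est$loglik + 1e-9, ll_at(0))
  expect_gte(est$loglik + 1e-9, ll_at(1))
})

test_that("lambda=0 PGLS equals OLS on the same design", {
  sim <- sim_study_traits(sim_config(seed = 11))
  dat <- sim$traits[sim$traits$sex == "female", ]
  fit <- pgls(dat, "brightness", c("bg_brightness", "pdt", "pwt"),
              sim$tree, lambda = 0)
  ols <- lm(log(brightness) ~ log(bg_brightness) + log(pdt) + log(pwt),
            data = dat)
  expect_equal(unname(fit$terms$estimate), unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("pgls reports Wald t, type-II F, GLS R2 and df bookkeeping", {
  sim <- sim_study_traits(sim_config(seed = 21, n_taxa = 17))
  dat <- sim$traits[sim$traits$sex == "female", ]
  fit <- pgls(dat, "saturation", c("bg_saturation", "pdt", "pwt"), sim$tree)
  expect_equal(fit$df_model, 3)
  expect_equal(fit$df_residual, 13)
  expect_equal(fit$df_model + fit$df_residual + 1, fit$n)
  expect_true(all(is.finite(fit$terms$t)))
  expect_true(fit$r.squared >= 0 && fit$r.squared <= 1)
  # fixed-lambda pgls agrees with gls_fit on the transformed covariance
  fit05 <- pgls(dat, "saturation", c("bg_saturation", "pdt", "pwt"),
                sim$tree, lambda = 0.5)
  dat2 <- dat[match(sim$tree$tip.label, dat$taxon), ]
  X <- cbind(1, log(dat2$bg_saturation), log(dat2$pdt), log(dat2$pwt))
  direct <- gls_fit(X, log(dat2$saturation),
                    lambda_transform(phylo_covariance(sim$tree), 0.5))
  expect_equal(unname(fit05$terms$estimate), unname(direct$coefficients),
               tolerance = 1e-10)
  # ln transform rejects non-positive values with taxon and column named
  bad <- dat; bad$pdt[3] <- -1
  expect_error(pgls(bad, "saturation", c("bg_saturation", "pdt", "pwt"),
                    sim$tree), "pdt")
})

test_that("pgls CI covers a true slope at near-nominal rate", {
  hits <- 0L
  n_rep <- 200L
  for (seed in seq_len(n_rep)) {
    tr <- random_tree(17, seed = 3000 + seed)
    set.seed(seed)
    x <- sim_bm_trait(tr, 1, 1)
    y <- 0.5 + 1 * x + sim_bm_trait(tr, 1, 0.25)
    dat <- data.frame(taxon = tr$tip.label, x = exp(x), y = exp(y))
    fit <- pgls(dat, "y", "x", tr)
    b <- fit$terms$estimate[2]
    half <- qt(0.975, fit$df_residual) * fit$terms$se[2]
    if (b - half <= 1 && 1 <= b + half) hits <- hits + 1L
  }
  # binomial se at 0.95 with 200 reps is ~1.5%; ML-lambda estimation at
  # n = 17 costs a little coverage
  expect_gt(hits / n_rep, 0.88)
  expect_lte(hits / n_rep, 1)
})

test_that("Benjamini-Hochberg step-up matches hand-computed adjustments", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand step-up: sorted q_i = min_{j>=i} m p_j / j
  p <- c(0.005, 0.04, 0.03, 0.9)
  expect_equal(bh_adjust(p), c(0.02, 4 * 0.04 / 3, 4 * 0.04 / 3, 0.9))
  set.seed(6)
  pr <- runif(25)
  q <- bh_adjust(pr)
  expect_true(all(q >= pr - 1e-15) && all(q <= 1))
  # permutation invariance after realignment
  perm <- sample(25)
  expect_equal(bh_adjust(pr[perm]), q[perm])
  expect_error(bh_adjust(c(0.1, 1.4)), "\\[0, 1\\]")
})
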