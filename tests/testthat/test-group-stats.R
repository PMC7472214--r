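test_that("correlations reproduce degenerate and hand-computed cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(correlation(x, x)$r, 1)
  expect_error(correlation(x, rep(1, 6)), "constant")

  # residualization on an orthogonal control is a no-op for r
  z <- c(1, -1, 1, -1, 1, -1)
  xo <- x - mean(x)
  xo <- xo - z * sum(xo * z) / sum(z * z)   # force exact orthogonality to z
  y <- c(2, 1, 4, 3, 6, 5) - mean(c(2, 1, 4, 3, 6, 5))
  y <- y - z * sum(y * z) / sum(z * z)
  expect_equal(correlation(xo, y, control = cbind(z))$r,
               correlation(xo, y)$r, tolerance = 1e-10)

  # fixed 6-point dataset: partial r via an independent lm-residual route
  set.seed(2)
  xs <- c(0.8, 1.6, 2.1, 3.3, 3.9, 5.2)
  ys <- c(1.1, 1.9, 3.4, 3.0, 5.2, 5.9)
  cs <- c(0.3, 1.2, 0.8, 2.4, 1.7, 2.9)
  oracle <- cor(residuals(lm(xs ~ cs)), residuals(lm(ys ~ cs)))
  rep_xy <- correlation(xs, ys, control = cbind(c = cs))
  expect_equal(rep_xy$r, oracle, tolerance = 1e-12)
  expect_identical(rep_xy$df, 6L - 2L - 1L)
  expect_identical(rep_xy$partial_on, "c")
})

test_that("Fisher confidence intervals bracket the point estimate and match cor.test", {
  set.seed(8)
  x <- rnorm(45); y <- 0.4 * x + rnorm(45)
  rep0 <- correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(rep0$r, unname(ct$estimate))
  expect_equal(rep0$p, ct$p.value, tolerance = 1e-12)
  expect_equal(rep0$ci95, as.numeric(ct$conf.int), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_true(rep0$ci95[1] <= rep0$r && rep0$r <= rep0$ci95[2])
})

test_that("standardized regression matches simple correlations for orthogonal designs", {
  n <- 40
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)   # exactly orthogonal to x1
  set.seed(3)
  y <- 0.5 * x1 - 0.3 * x2 + rnorm(n)
  rep1 <- standardized_regression(y, data.frame(x1 = x1, x2 = x2))
  expect_equal(rep1$coefficients$vif, c(1, 1), tolerance = 1e-10)
  expect_equal(rep1$coefficients$estimate,
               c(cor(y, x1), cor(y, x2)), tolerance = 1e-10)
  ci_ok <- with(rep1$coefficients, ci_lo <= estimate & estimate <= ci_hi)
  expect_true(all(ci_ok))
})

test_that("rank-deficient and constant designs raise collinearity errors", {
  set.seed(4)
  x <- rnorm(20)
  expect_error(standardized_regression(rnorm(20),
                                       data.frame(a = x, b = x)), "collinear")
  expect_error(standardized_regression(rnorm(20),
                                       data.frame(a = x, b = rep(2, 20))),
               "constant")
})

test_that("VIFs equal the auxiliary-regression formula and an external oracle", {
  set.seed(5)
  n <- 45
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  X$c <- 0.7 * X$a + 0.5 * X$b + rnorm(n, sd = 0.6)
  y <- X$a + rnorm(n)
  rep2 <- standardized_regression(y, X)

  # direct auxiliary-regression oracle
  Xz <- scale(as.matrix(X))
  vif_oracle <- sapply(1:3, function(j) {
    r2 <- summary(lm(Xz[, j] ~ Xz[, -j]))$r.squared
    1 / (1 - r2)
  })
  expect_equal(rep2$coefficients$vif, vif_oracle, tolerance = 1e-10)

  # independent implementation in the car package
  if (requireNamespace("car", quietly = TRUE)) {
    fit <- lm(y ~ a + b + c, data = X)
    expect_equal(rep2$coefficients$vif, unname(car::vif(fit)),
                 tolerance = 1e-8)
  }
})

test_that("VIF screening uses a strict threshold", {
  set.seed(6)
  n <- 50
  a <- rnorm(n)
  X <- data.frame(a = a, b = a + rnorm(n, sd = sqrt(1 / 500)))  # r ~ 0.999
  rep3 <- standardized_regression(rnorm(n) + a, X)
  expect_true(all(vif_screen(rep3)))
  expect_false(any(vif_screen(rep3, threshold = max(rep3$coefficients$vif))))
})

test_that("group differences match hand computation and simulation", {
  h <- group_difference(c(1, 2, 3), c(3, 4, 5))
  expect_equal(h$cohens_d, -2)
  expect_equal(h$t, -2 / sqrt(2 / 3), tolerance = 1e-12)

  same <- group_difference(c(1, 2, 3), c(1, 2, 3), tail = "one")
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p, 0.5)

  expect_error(group_difference(c(1, 1), c(1, 1)), "degenerate")

  set.seed(7)
  d_hat <- group_difference(rnorm(1e4), rnorm(1e4, mean = 1))$cohens_d
  expect_lt(abs(d_hat + 1), 0.05)
})

test_that("standardized coefficients are invariant to affine predictor rescaling", {
  set.seed(9)
  n <- 45
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- X$a - 0.5 * X$b + rnorm(n)
  r1 <- standardized_regression(y, X)
  X2 <- data.frame(a = 100 * X$a - 7, b = 0.001 * X$b + 3)
  r2 <- standardized_regression(10 * y + 2, X2)
  expect_equal(r1$coefficients$estimate, r2$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(r1$coefficients$vif, r2$coefficients$vif, tolerance = 1e-10)
  expect_equal(r1$adj_r2, r2$adj_r2, tolerance = 1e-10)
})

test_that("BIC model comparison prefers parsimony against pure-noise predictors", {
  set.seed(10)
  n <- 500
  x <- rnorm(n); noise <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  small <- standardized_regression(y, data.frame(x = x))
  big <- standardized_regression(y, data.frame(x = x, noise = noise))
  tab <- compare_models_bic(list(small = small, big = big))
  expect_identical(tab$model[1], "small")
  expect_equal(tab$delta_bic[1], 0)
  expect_identical(compare_models_bic(list(m = small, m2 = small))$delta_bic,
                   c(0, 0))
  tiny <- standardized_regression(y[1:50], data.frame(x = x[1:50]))
  expect_error(compare_models_bic(list(small, tiny)), "different numbers")
})

test_that("the full covariate model wins the value-signal comparison in most replicates", {
  hits <- 0
  for (s in 1:30) {
    co <- generate_cohort(default_study_spec(), seed = 100 + s)
    az <- as.integer(co$age_group == "old")
    preds <- data.frame(age = az, fa = co$fa, bpnd = co$bpnd)
    tab <- compare_models_bic(list(
      full = standardized_regression(co$q_signal, preds),
      age_fa = standardized_regression(co$q_signal, preds[c("age", "fa")]),
      age_bpnd = standardized_regression(co$q_signal, preds[c("age", "bpnd")])))
    hits <- hits + (tab$model[1] == "full")
  }
  expect_gt(hits, 15)
})

test_that("residual-normality gate reflects the Shapiro-Wilk p-value", {
  set.seed(12)
  n <- 60
  x <- rnorm(n)
  good <- standardized_regression(x + rnorm(n), data.frame(x = x))
  expect_identical(good$normality_ok, good$shapiro_p > 0.05)
  bad <- standardized_regression(x + rlnorm(n, sd = 1.5), data.frame(x = x))
  expect_lte(bad$shapiro_p, 0.05)
  expect_false(bad$normality_ok)
})
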