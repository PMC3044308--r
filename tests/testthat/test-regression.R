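test_that("log_expression is a monotone shifted log", {
  expect_equal(log_expression(1), log10(1.01))
  expect_equal(log_expression(0), -2)
  y <- sort(runif(20, 0, 50))
  expect_true(all(diff(log_expression(y)) > 0))
  expect_error(log_expression(1, pseudocount = 0), "positive")
})

test_that("fit_ols recovers exact linear structure and drops aliased columns", {
  x1 <- 1:10
  y <- 2 * x1 + 3
  f <- fit_ols(cbind(x1 = x1), y)
  expect_equal(unname(f$coefficients["x1"]), 2, tolerance = 1e-10)
  expect_equal(f$intercept, 3, tolerance = 1e-10)
  expect_equal(f$rss, 0, tolerance = 1e-16)

  # duplicated column: one dropped, fit unchanged
  set.seed(6)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X2 <- cbind(X, a2 = X[, "a"])
  y2 <- X[, "a"] - X[, "b"] + rnorm(30, 0, 0.1)
  f1 <- fit_ols(X, y2)
  f2 <- fit_ols(X2, y2)
  expect_equal(length(f2$dropped), 1L)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-12)
})

test_that("fit_ols matches the normal-equations oracle with orthogonal residuals", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(250), 50, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    y <- rnorm(50)
    f <- fit_ols(X, y)
    Xi <- cbind(1, X)
    beta <- unname(drop(solve(t(Xi) %*% Xi, t(Xi) %*% y)))
    expect_equal(unname(coef(f)), beta, tolerance = 1e-10)
    expect_lt(max(abs(t(Xi) %*% f$residuals)), 1e-8)
    expect_lt(abs(sum(f$residuals)), 1e-8)
    # AIC is the Gaussian profile form
    expect_equal(f$aic, 50 * log(f$rss / 50) + 2 * 6, tolerance = 1e-12)
  }
})

test_that("cross_validate is seed-deterministic and calibrated at the extremes", {
  set.seed(7)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -2, 0.5)
  cv <- cross_validate(X, drop(y), seed = 5)
  expect_gte(cv$cv_r, 0.999)
  expect_identical(cross_validate(X, drop(y), seed = 5), cv)
  expect_length(cv$per_run, 10L)

  # label permutation: no predictive signal
  set.seed(8)
  X0 <- matrix(rnorm(500 * 12), 500, 12,
               dimnames = list(NULL, paste0("v", 1:12)))
  y0 <- rnorm(500)
  low <- vapply(1:3, function(s)
    cross_validate(X0, y0, seed = s)$cv_r2, numeric(1))
  expect_true(all(low < 0.05))
})

test_that("stepwise selection keeps planted variables and tolerates pure noise", {
  hits <- 0L
  for (s in 1:8) {
    set.seed(s)
    X <- matrix(rnorm(1000 * 10), 1000, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
    y <- X[, 1] + 0.8 * X[, 4] - X[, 7] + rnorm(1000, 0, 0.3)
    sel <- stepwise_select(X, y)
    if (all(c("v1", "v4", "v7") %in% sel$retained)) hits <- hits + 1L
  }
  expect_gte(hits, 7L)

  set.seed(9)
  Xn <- matrix(rnorm(200 * 4), 200, 4,
               dimnames = list(NULL, paste0("n", 1:4)))
  sel0 <- stepwise_select(Xn, rnorm(200))
  expect_true(length(sel0$retained) <= 4)   # intercept-only permitted
})

test_that("expr_regression ties the methods together", {
  sim <- simulate_study(n_genes = 300, seed = 21)
  fit <- expr_regression(sim$design, sim$y, seed = 21)
  expect_s3_class(fit, "expr_regression")
  expect_equal(length(residuals(fit)), 300L)
  expect_equal(predict(fit), fit$fit$fitted)
  expect_equal(unname(predict(fit, sim$design)), unname(fit$fit$fitted),
               tolerance = 1e-10)
  expect_equal(names(coef(fit))[1], "(Intercept)")
  expect_true(fit$cv$cv_r2 >= 0 && fit$cv$cv_r2 <= 1)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.expr_regression")
  expect_output(print(fit), "CV-R")

  # stepwise variant exposes the retained set
  fit_sw <- expr_regression(sim$design, sim$y, seed = 21, stepwise = TRUE)
  expect_true(length(fit_sw$variables) <= ncol(sim$design$values))
})

test_that("planted coefficients are recovered within 3 SE on synthetic data", {
  ok <- 0L
  total <- 0L
  for (s in 1:5) {
    sim <- simulate_study(n_genes = 800, seed = 100 + s)
    f <- fit_ols(sim$design, sim$y)
    truth <- c("(Intercept)" = sim$truth$intercept, sim$truth$coefficients)
    est <- coef(f)[names(truth)]
    se <- f$se[names(truth)]
    ok <- ok + sum(abs(est - truth) <= 3 * se)
    total <- total + length(truth)
  }
  expect_gte(ok / total, 0.95)
})
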