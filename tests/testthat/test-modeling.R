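test_that("metrics match hand arithmetic and the identities", {
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(perfect), c(1, 0, 0))

  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(unname(m["rmse"]), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(unname(m["nrmse"]), sqrt(1 / 3) / 2, tolerance = 1e-12)
  expect_equal(round(100 * unname(m["nrmse"]), 1), 28.9)

  # mean-only predictor has R2 exactly 0
  y <- c(0.9, 1.4, 2.2, 2.8)
  m0 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(unname(m0["r2"]), 0, tolerance = 1e-12)

  expect_error(regression_metrics(c(-1, 1), c(0, 0)), "mean")
  expect_error(regression_metrics(c(2, 2), c(1, 3)), "constant")
})

test_that("descriptive statistics reproduce the published CV arithmetic", {
  # two-point vectors carry exact target moments: mean m, sd s
  two_point <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))
  cal <- descriptive_stats(two_point(1.91, 0.59))
  expect_equal(round(unname(cal["cv"]), 2), 0.31)
  val <- descriptive_stats(two_point(1.81, 0.65))
  expect_equal(round(unname(val["cv"]), 2), 0.36)
  expect_equal(unname(descriptive_stats(c(2, 2, 2))["cv"]), 0)
  expect_equal(unname(descriptive_stats(c(1, 5))[c("max", "min", "mean")]),
               c(5, 1, 3))
})

test_that("full-component PLS equals OLS on well-conditioned data", {
  set.seed(2)
  X <- rand_design(40, 2, seed = 2)
  y <- 1.5 + X %*% c(2, -1) + rnorm(40, sd = 0.2)
  pls <- fit_pls(X, y, ncomp = 2)
  ols <- lm.fit(cbind(1, X), y)
  expect_equal(predict(pls, X), unname(ols$fitted.values), tolerance = 1e-8)
  expect_equal(unname(pls$coefficients), unname(coef(ols)), tolerance = 1e-8)
})

test_that("PLS predictions are affine-equivariant in y", {
  X <- rand_design(30, 3, seed = 6)
  y <- X %*% c(1, 0.5, -2) + rnorm(30, sd = 0.1)
  p1 <- predict(fit_pls(X, y, ncomp = 3), X)
  p2 <- predict(fit_pls(X, y + 10, ncomp = 3), X)
  expect_equal(p2, p1 + 10, tolerance = 1e-8)
})

test_that("PLS tolerates exactly collinear columns", {
  X <- rand_design(25, 3, seed = 10)
  X <- cbind(X, x04 = X[, "x03"])
  y <- X[, "x01"] + rnorm(25, sd = 0.1)
  fit <- fit_pls(X, y, ncomp = 2)
  expect_length(predict(fit, X), 25)
  expect_true(all(is.finite(predict(fit, X))))
})

test_that("single-predictor PLS is simple least squares", {
  X <- rand_design(20, 1, seed = 14)
  y <- 3 * X[, 1] + rnorm(20, sd = 0.1)
  fit <- fit_pls(X, y)
  expect_equal(fit$ncomp, 1)
  expect_equal(predict(fit, X),
               unname(lm.fit(cbind(1, X), y)$fitted.values), tolerance = 1e-10)
})

test_that("PLS training RMSE is non-increasing in component count", {
  set.seed(18)
  X <- rand_design(30, 5, seed = 18)
  y <- X %*% c(1, -1, 0.5, 0, 0) + rnorm(30, sd = 0.3)
  rmse <- vapply(1:4, function(k) {
    fit <- fit_pls(X, y, ncomp = k)
    regression_metrics(as.numeric(y), predict(fit, X))[["rmse"]]
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-8))
})

test_that("PLS validation RMSE approaches the noise floor", {
  set.seed(22)
  sigma <- 0.3
  X <- matrix(rnorm(200 * 5), 200, 5)
  colnames(X) <- paste0("x", 1:5)
  y <- X %*% c(1, -0.5, 0.8, 0.3, -1) + rnorm(200, sd = sigma)
  tr <- 1:150
  fit <- fit_pls(X[tr, ], y[tr])
  val_rmse <- regression_metrics(as.numeric(y[-tr]),
                                 predict(fit, X[-tr, ]))[["rmse"]]
  expect_lt(abs(val_rmse - sigma) / sigma, 0.15)
})

test_that("random forest fits are deterministic given the seed", {
  X <- rand_design(30, 4, seed = 26)
  y <- X[, "x01"] + rnorm(30, sd = 0.2)
  f1 <- fit_rf(X, y, ntree = 100, seed = 7)
  f2 <- fit_rf(X, y, ntree = 100, seed = 7)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_equal(f1$oob_rmse, f2$oob_rmse)
})

test_that("a dominant predictor ranks first in forest importance", {
  set.seed(30)
  X <- rand_design(60, 4, seed = 30)
  y <- 3 * X[, "x01"] + rnorm(60, sd = 0.1)
  fit <- fit_rf(X, y, ntree = 300, seed = 3)
  expect_identical(names(which.max(fit$importance)), "x01")
})

test_that("pure-noise responses give near-zero out-of-bag R2", {
  r2 <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 5), 40, 5)
    colnames(X) <- paste0("x", 1:5)
    y <- rnorm(40)
    fit <- fit_rf(X, y, ntree = 200, seed = s)
    1 - fit$oob_rmse^2 / mean((y - mean(y))^2)
  }, numeric(1))
  expect_lt(mean(r2), 0.1)
  expect_gt(mean(r2), -0.6)
})

test_that("model reports enforce the NRMSE identity", {
  X <- rand_design(24, 3, seed = 34)
  y <- 2 + X[, "x01"] + rnorm(24, sd = 0.2)
  tr <- 1:16
  fit <- fit_pls(X[tr, ], y[tr], ncomp = 2)
  cal <- evaluate_model(fit, X[tr, ], y[tr])
  val <- evaluate_model(fit, X[-tr, ], y[-tr])
  rep_ <- model_report("toy", "PLS", cal, val, 16, 8, y[tr], y[-tr])
  expect_equal(rep_$nrmse, rep_$rmse / c(mean(y[tr]), mean(y[-tr])),
               tolerance = 1e-12)
  expect_equal(nrow(rep_), 2)
})
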