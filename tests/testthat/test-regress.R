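test_that("noiseless linear data is recovered exactly", {
  d <- data.frame(vbsa = seq(40, 120, length.out = 30))
  d$wbsa <- 2 * d$vbsa + 3
  fit <- suppressWarnings(wbsa_model(wbsa ~ vbsa, d, k = 5, seed = 1))
  expect_equal(unname(coef(fit)), c(3, 2), tolerance = 1e-9)
  expect_lt(fit$cv$rmse, 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)

  # two points, one predictor: exact interpolation
  d2 <- data.frame(vbsa = c(50, 100), wbsa = c(110, 220))
  f2 <- stats::lm(wbsa ~ vbsa, d2)
  expect_equal(unname(stats::predict(f2, d2)), d2$wbsa, tolerance = 1e-9)
})

test_that("planted coefficients are recovered within 3 SE at n = 5000", {
  set.seed(101)
  n <- 5000
  d <- data.frame(vbsa = stats::runif(n, 40, 140),
                  stature = stats::runif(n, 120, 220))
  d$wbsa <- 1.9 * d$vbsa + 0.3 * d$stature + 5 + stats::rnorm(n)
  fit <- wbsa_model(wbsa ~ vbsa + stature, d, k = 10, seed = 2)
  se <- summary(fit$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(coef(fit)["vbsa"] - 1.9), 3 * se["vbsa"])
  expect_lt(abs(coef(fit)["stature"] - 0.3), 3 * se["stature"])
  expect_lt(abs(coef(fit)["(Intercept)"] - 5), 3 * se["(Intercept)"])

  # independent oracle: normal equations solved directly
  X <- cbind(1, d$vbsa, d$stature)
  beta <- solve(t(X) %*% X, t(X) %*% d$wbsa)
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-8)
  # residual orthogonality of the OLS solution
  r <- residuals(fit)
  expect_lt(max(abs(t(X) %*% r)) / n, 1e-8)
})

test_that("cross-validation error matches the noise floor", {
  set.seed(77)
  n <- 5000
  d <- data.frame(vbsa = stats::runif(n, 40, 140))
  d$wbsa <- 2.2 * d$vbsa + 10 + stats::rnorm(n, 0, 2)
  cv <- cross_validate(d, wbsa ~ vbsa, k = 10, seed = 3)
  expect_gt(cv$rmse, 1.9)
  expect_lt(cv$rmse, 2.1)
  expect_equal(cv$rmse^2, cv$mspe, tolerance = 1e-12)

  cv2 <- cross_validate(d, wbsa ~ vbsa, k = 10, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$rmse, cv2$rmse)
  expect_error(cross_validate(d[1:5, ], wbsa ~ vbsa, k = 10), "k must not")
  expect_error(cross_validate(d, wbsa ~ vbsa, k = 1), "k must be")
})

test_that("cross-validated error is no more optimistic than in-sample error", {
  set.seed(5)
  rmses <- vapply(1:20, function(s) {
    d <- data.frame(vbsa = stats::runif(200, 40, 140))
    d$wbsa <- 2 * d$vbsa + 5 + stats::rnorm(200, 0, 3)
    fit <- wbsa_model(wbsa ~ vbsa, d, k = 10, seed = s)
    c(fit$cv$rmse, fit$residual_se)
  }, numeric(2))
  expect_gt(mean(rmses[1, ]), mean(rmses[2, ]) * 0.99)
})

test_that("rank-deficient designs fail loudly naming the columns", {
  d <- data.frame(vbsa = 1:20)
  d$twice <- 2 * d$vbsa
  d$wbsa <- d$vbsa + stats::rnorm(20)
  expect_error(wbsa_model(wbsa ~ vbsa + twice, d, cv = FALSE), "twice")
})

test_that("Spearman matrix matches the brute-force rank formula", {
  x <- c(1, 5, 2, 2, 9, 4)
  y <- c(2, 7, 3, 1, 10, 10)
  z <- c(3, 1, 4, 1, 5, 9)
  m <- spearman_matrix(data.frame(x = x, y = y, z = z))
  # oracle: Pearson correlation of average ranks, computed by hand
  rho_oracle <- function(a, b) {
    ra <- rank(a, ties.method = "average")
    rb <- rank(b, ties.method = "average")
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  expect_equal(m["x", "y"], rho_oracle(x, y), tolerance = 1e-12)
  expect_equal(m["x", "z"], rho_oracle(x, z), tolerance = 1e-12)
  expect_equal(diag(unclass(m)), c(x = 1, y = 1, z = 1))
  expect_equal(unclass(m), t(unclass(m)))

  expect_equal(spearman_matrix(data.frame(a = 1:9, b = (1:9)^3))["a", "b"], 1)
  expect_equal(spearman_matrix(data.frame(a = 1:9, b = -(1:9)))["a", "b"], -1)
  expect_warning(mc <- spearman_matrix(data.frame(a = 1:5, b = rep(2, 5))),
                 "constant")
  expect_true(is.na(mc["a", "b"]))
})

test_that("grouped fits recover group-specific slopes and guard small groups", {
  set.seed(9)
  n <- 400
  g <- rep(c("A", "B"), each = n / 2)
  vb <- stats::runif(n, 40, 140)
  wb <- ifelse(g == "A", 2 * vb + 5, 3.5 * vb - 10) + stats::rnorm(n)
  d <- data.frame(vbsa = vb, wbsa = wb, grp = g)

  fits <- fit_by_group(d, wbsa ~ vbsa, "grp", k = 5, seed = 1)
  expect_named(fits, c("A", "B"))
  expect_equal(unname(coef(fits$A)["vbsa"]), 2, tolerance = 0.05)
  expect_equal(unname(coef(fits$B)["vbsa"]), 3.5, tolerance = 0.05)

  one <- fit_by_group(d, wbsa ~ vbsa, rep("all", n), k = 5, seed = 1)$all
  whole <- wbsa_model(wbsa ~ vbsa, d, k = 5, seed = 1)
  expect_equal(coef(one), coef(whole))

  d$tiny <- c(rep("big", n - 3), rep("small", 3))
  expect_warning(ft <- fit_by_group(d, wbsa ~ vbsa, "tiny", k = 5, seed = 1),
                 "skipped")
  expect_named(ft, "big")
  expect_error(fit_by_group(d, wbsa ~ vbsa, rep(NA_character_, n)), "empty")
})

test_that("residual diagnostics expose homo- and heteroscedasticity", {
  set.seed(21)
  d <- data.frame(vbsa = stats::runif(300, 40, 140))
  d$wbsa <- 2 * d$vbsa + 5
  exact <- suppressWarnings(wbsa_model(wbsa ~ vbsa, d, cv = FALSE))
  expect_lt(max(abs(residual_diagnostics(exact)$table$residual)), 1e-9)

  # homoscedastic noise: variance-trend test rarely fires at alpha = 0.01
  hits <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    dd <- data.frame(vbsa = stats::runif(150, 40, 140))
    dd$wbsa <- 2 * dd$vbsa + 5 + stats::rnorm(150, 0, 2)
    residual_diagnostics(
      wbsa_model(wbsa ~ vbsa, dd, cv = FALSE))$bp$p.value < 0.01
  }, TRUE)
  expect_lte(mean(hits), 0.05)

  # variance growing with the response is flagged
  set.seed(33)
  dh <- data.frame(vbsa = stats::runif(500, 40, 140))
  dh$wbsa <- 2 * dh$vbsa + 5 + stats::rnorm(500, 0, 0.02 * (2 * dh$vbsa + 5))
  diag_h <- residual_diagnostics(wbsa_model(wbsa ~ vbsa, dh, cv = FALSE))
  expect_lt(diag_h$bp$p.value, 0.01)
  tab <- diag_h$table
  expect_equal(nrow(tab), 500)
  expect_equal(sort(tab$theoretical_quantile),
               stats::qnorm(stats::ppoints(500)), tolerance = 1e-9)
})

test_that("model object methods behave like a standard fitted model", {
  set.seed(3)
  d <- data.frame(vbsa = stats::runif(100, 40, 140))
  d$wbsa <- 2 * d$vbsa + 5 + stats::rnorm(100)
  fit <- wbsa_model(wbsa ~ vbsa, d, k = 5, seed = 1, theta = 30, phi = 0)
  expect_s3_class(fit, "wbsa_model")
  expect_length(coef(fit), 2)
  expect_equal(unname(predict(fit, data.frame(vbsa = 100))),
               unname(coef(fit)[1] + 100 * coef(fit)[2]), tolerance = 1e-9)
  expect_equal(length(residuals(fit)), 100)
  expect_equal(nrow(simulate(fit, nsim = 2, seed = 1)), 100)
  expect_output(print(fit), "theta 30")
  expect_output(print(summary(fit)), "CV")
  tab <- angle_fit_table(fit, model = "vbsa")
  expect_equal(tab$theta, 30)
  expect_true(all(c("c0", "c1", "cv_rmse", "cv_mspe", "cv_mape") %in%
                    names(tab)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
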