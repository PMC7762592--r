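test_that("a noiseless power law is recovered exactly", {
  t <- c(4, 7, 9, 12, 13, 16, 27)
  fit <- fit_allometric(t, 10^0.37 * t^1.47, "genome_kbp")
  expect_equal(fit$log10_a, 0.37, tolerance = 1e-10)
  expect_equal(fit$b, 1.47, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_identical(fit$n, 7L)
  expect_identical(fit$df, 5L)
})

test_that("per-T averaging happens in linear space before logging", {
  # two replicates per T whose arithmetic mean lies on the power law
  t <- rep(c(4, 9, 16), each = 2)
  mu <- 2 * c(4, 9, 16)^1.5
  y <- as.vector(rbind(mu * 1.5, mu * 0.5))  # mean is mu, geometric mean is not
  fit <- fit_allometric(t, y, "genome_kbp")
  expect_equal(fit$b, 1.5, tolerance = 1e-10)
  expect_equal(10^fit$log10_a, 2, tolerance = 1e-10)
})

test_that("fitting validates its inputs", {
  expect_error(fit_allometric(c(1, 2), c(1, 2), "genome_kbp"), "3 distinct")
  expect_error(fit_allometric(c(1, 2, 3), c(1, -2, 3), "genome_kbp"),
               "positive")
  # values independent of T: flat line, negligible explained variance
  set.seed(100)
  t <- c(1, 2, 4, 8, 16, 32)
  fit0 <- fit_allometric(t, 5 * 10^rnorm(6, 0, 0.02), "genome_kbp")
  expect_lt(abs(fit0$b), 0.1)
  expect_lt(fit0$r_squared, 0.5)
})

test_that("95% parameter CIs cover the true exponent at the nominal rate", {
  t <- c(4, 7, 9, 12, 13, 16, 27)
  mu <- 10^0.37 * t^1.47
  set.seed(421)
  covered <- vapply(1:500, function(i) {
    y <- mu * 10^rnorm(length(t), 0, 0.05)
    fit <- fit_allometric(t, y, "genome_kbp")
    half <- qt(0.975, fit$df) * fit$se_b
    abs(fit$b - 1.47) <= half
  }, logical(1))
  expect_equal(mean(covered), 0.95, tolerance = 0.035)
})

test_that("printed parameters reproduce the published predictions", {
  g <- printed_genome_fit()
  expect_equal(predict_mean(g, 1), 2.34, tolerance = 0.01)
  expect_equal(predict_mean(g, 3), 11.78, tolerance = 0.01)
  expect_equal(predict_mean(g, 4), 17.98, tolerance = 0.01)
  d <- printed_diameter_fit()
  expect_equal(predict_mean(d, 3), 42.76, tolerance = 0.01)
  # CV of the genome exponent: 0.09 / 1.47
  expect_equal(unname(coef_cv(g)["exponent"]), 0.061, tolerance = 0.01)
  # packaged parameter file carries the same models
  pp <- printed_params()
  expect_equal(predict_mean(pp$genome_kbp, 1), predict_mean(g, 1))
  expect_equal(predict_mean(pp$diameter_nm, 3), predict_mean(d, 3))
})

test_that("inverse_t inverts predict_mean", {
  g <- printed_genome_fit()
  expect_equal(inverse_t(g, 2.34), 1, tolerance = 2e-3)
  expect_equal(inverse_t(g, predict_mean(g, 7)), 7, tolerance = 1e-9)
  expect_equal(inverse_t(g, 44.8), 7.44, tolerance = 0.01)
  expect_error(inverse_t(g, -1), "positive")
  expect_error(predict_mean(g, 0), "positive")
})

test_that("interval formula matches the standard regression machinery", {
  t <- c(4, 7, 9, 12, 13, 16, 27)
  set.seed(7)
  y <- 10^0.37 * t^1.47 * 10^rnorm(7, 0, 0.05)
  fit <- fit_allometric(t, y, "genome_kbp")
  lmfit <- lm(log10(y) ~ log10(t))
  newx <- data.frame(t = c(1, 3, 20))
  for (kind in c("mean_response", "new_observation")) {
    mine <- predict_interval(fit, newx$t, 0.95, kind)
    ref <- predict(lmfit, data.frame(t = newx$t),
                   interval = if (kind == "mean_response") "confidence"
                              else "prediction", level = 0.95)
    expect_equal(mine$mean, unname(10^ref[, "fit"]), tolerance = 1e-9)
    expect_equal(mine$lower, unname(10^ref[, "lwr"]), tolerance = 1e-9)
    expect_equal(mine$upper, unname(10^ref[, "upr"]), tolerance = 1e-9)
  }
})

test_that("interval widths behave like regression leverage", {
  t <- c(4, 7, 9, 12, 13, 16, 27)
  set.seed(11)
  y <- 10^0.37 * t^1.47 * 10^rnorm(7, 0, 0.05)
  fit <- fit_allometric(t, y, "genome_kbp")
  grid <- c(1, 2, 4, 8, 10^fit$mean_log10_t, 16, 32)
  ci <- predict_interval(fit, grid)
  expect_true(all(ci$lower < ci$mean & ci$mean < ci$upper))
  relw <- log10(ci$upper) - log10(ci$lower)
  expect_identical(which.min(relw), which(grid == 10^fit$mean_log10_t))
  # noiseless fit: intervals collapse
  fit0 <- fit_allometric(t, 10^0.37 * t^1.47, "genome_kbp")
  ci0 <- predict_interval(fit0, 3)
  expect_lt(ci0$upper / ci0$lower - 1, 1e-6)
  # evaluation-only fits cannot produce intervals
  expect_error(predict_interval(printed_genome_fit(), 3), "residual statistics")
})

test_that("prediction intervals contain mean-response intervals", {
  t <- c(4, 7, 9, 12, 13, 16, 27)
  set.seed(3)
  y <- 10^0.37 * t^1.47 * 10^rnorm(7, 0, 0.05)
  fit <- fit_allometric(t, y, "genome_kbp")
  cm <- predict_interval(fit, 3, kind = "mean_response")
  cn <- predict_interval(fit, 3, kind = "new_observation")
  expect_lt(cn$lower, cm$lower)
  expect_gt(cn$upper, cm$upper)
})

test_that("fits are scale-equivariant and monotone for positive exponents", {
  t <- c(4, 7, 9, 12, 13, 16, 27)
  set.seed(5)
  y <- 10^0.37 * t^1.47 * 10^rnorm(7, 0, 0.03)
  f1 <- fit_allometric(t, y, "genome_kbp")
  f2 <- fit_allometric(t, 1000 * y, "genome_kbp")
  expect_equal(f2$b, f1$b, tolerance = 1e-12)
  expect_equal(f2$log10_a - f1$log10_a, 3, tolerance = 1e-12)
  grid <- seq(0.5, 40, length.out = 200)
  expect_true(all(diff(predict_mean(f1, grid)) > 0))
})

test_that("residual diagnostics flag outliers and pass clean fits", {
  t <- c(4, 7, 9, 12, 13, 16, 27)
  fit0 <- fit_allometric(t, 2 * t^1.5, "genome_kbp")
  d0 <- residual_diagnostics(fit0)
  expect_equal(max(abs(d0$residuals)), 0, tolerance = 1e-12)
  set.seed(9)
  fitn <- fit_allometric(t, 2 * t^1.5 * 10^rnorm(7, 0, 0.05), "genome_kbp")
  dn <- residual_diagnostics(fitn)
  expect_true(all(abs(dn$standardized) < 3))
  expect_gt(dn$normality_p, 0.001)
  # a 10x outlier carries the largest standardized residual
  y <- 2 * t^1.5; y[4] <- y[4] * 10
  dout <- residual_diagnostics(fit_allometric(t, y, "genome_kbp"))
  expect_identical(unname(which.max(abs(dout$standardized))), 4L)
  expect_error(residual_diagnostics(printed_genome_fit()), "fresh fit")
})

test_that("the scaling argument gives exponents 3/2 and 1/2", {
  th <- theoretical_exponents()
  expect_equal(unname(th["b_g"]), 1.5, tolerance = 1e-9)
  expect_equal(unname(th["b_d"]), 0.5, tolerance = 1e-9)
})

test_that("fits serialize to JSON and back", {
  t <- c(4, 7, 9, 12, 16)
  set.seed(2)
  fit <- fit_allometric(t, 2 * t^1.5 * 10^rnorm(5, 0, 0.02), "genome_kbp")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(back$log10_a, fit$log10_a)
  expect_equal(back$b, fit$b)
  expect_equal(back$residual_sd, fit$residual_sd)
  expect_equal(predict_interval(back, 3), predict_interval(fit, 3),
               tolerance = 1e-12)
})
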