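test_that("skewness/kurtosis test matches an independent implementation", {
  # frozen reference values from an independent implementation of the
  # same D'Agostino/Anscombe-Glynn construction (scipy.stats
  # skewtest/kurtosistest/normaltest) on the identical samples
  set.seed(42)
  x <- rnorm(200)
  r <- skewness_kurtosis_test(x)
  expect_equal(r$skewness, -0.139866354854, tolerance = 1e-9)
  expect_equal(r$kurtosis, 3.103964183238, tolerance = 1e-9)
  expect_equal(r$z_skewness, -0.831778319576, tolerance = 1e-8)
  expect_equal(r$z_kurtosis, 0.539934827847, tolerance = 1e-8)
  expect_equal(r$statistic, 0.983384791238, tolerance = 1e-7)
  expect_equal(r$p_joint, 0.611590464807, tolerance = 1e-7)

  set.seed(7)
  y <- rexp(150)
  re <- skewness_kurtosis_test(y)
  expect_equal(re$skewness, 1.683034905899, tolerance = 1e-9)
  expect_equal(re$kurtosis, 6.112912063185, tolerance = 1e-9)
  expect_equal(re$z_skewness, 6.446001848173, tolerance = 1e-8)
  expect_equal(re$z_kurtosis, 4.027200427109, tolerance = 1e-8)
  expect_lt(re$p_joint, 1e-10)
})

test_that("skewness is exactly zero for a symmetric sample", {
  x <- rep(c(-2, -1, 0, 1, 2), 100)
  r <- skewness_kurtosis_test(x)
  expect_equal(r$skewness, 0)
  expect_equal(r$p_skewness, 1, tolerance = 1e-12)
})

test_that("normality test holds its size and detects strong skew", {
  # size under the null: 1,000 normal samples of size 10,000
  set.seed(123)
  rejections <- vapply(1:1000, function(i)
    skewness_kurtosis_test(rnorm(10000))$p_joint < 0.05, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
  # power against an exponential
  set.seed(321)
  expect_lt(skewness_kurtosis_test(rexp(10000))$p_joint, 0.001)
})

test_that("normality test rejects degenerate input", {
  expect_error(skewness_kurtosis_test(rep(3, 50)), "constant")
  expect_error(skewness_kurtosis_test(rnorm(5)), "at least 8")
})

test_that("Modified Park test recovers the variance power", {
  # variance directly proportional to the mean (covariates in shape)
  d1 <- simulate_shape_dgp(50000, seed = 61)
  mu1 <- exp(drop(d1$design %*% c(2, 0.05, 1)))
  p1 <- modified_park_test(d1$y, mu1)
  expect_gt(p1$lambda_hat, 0.8)
  expect_lt(p1$lambda_hat, 1.2)
  expect_gt(p1$p_vs[["lambda=1"]], 0.01)
  expect_lt(p1$p_vs[["lambda=2"]], 0.001)

  # variance proportional to the squared mean (covariates in scale)
  d2 <- simulate_scale_dgp(50000, theta = c(2, 0, 1), log_alpha = 3,
                           seed = 62)
  mu2 <- exp(3) * exp(drop(d2$design %*% c(2, 0, 1)))
  p2 <- modified_park_test(d2$y, mu2)
  expect_gt(p2$lambda_hat, 1.8)
  expect_lt(p2$lambda_hat, 2.2)
  expect_lt(p2$p_vs[["lambda=1"]], 0.001)

  # homoskedastic data: power zero
  set.seed(63)
  x <- runif(50000, 0, 2)
  mu3 <- 20 + 5 * x
  y3 <- mu3 + rnorm(50000)
  p3 <- modified_park_test(y3, mu3)
  expect_lt(abs(p3$lambda_hat), 0.2)
})

test_that("Park test OLS variant runs and inputs are validated", {
  d <- simulate_shape_dgp(2000, seed = 64)
  mu <- exp(drop(d$design %*% c(2, 0.05, 1)))
  pk <- modified_park_test(d$y, mu, method = "ols")
  expect_true(is.finite(pk$lambda_hat))
  expect_gt(pk$se_lambda, 0)
  expect_error(modified_park_test(d$y, mu - max(mu)), "positive")
  expect_error(modified_park_test(d$y, mu[-1]), "length")
})

test_that("prediction metrics match hand computations", {
  y <- c(1, 2, 3, 4)
  yhat <- c(2, 2, 2, 4)
  m <- prediction_metrics(y, yhat)
  expect_equal(m$rmse, sqrt(2 / 4))
  # population variances: residuals (-1,0,1,0) -> 0.5; y -> 1.25
  expect_equal(m$r_squared, 1 - 0.5 / 1.25)

  set.seed(71)
  y2 <- rgamma(100, 2, 1)
  perfect <- prediction_metrics(y2, y2)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)
  expect_true(all(perfect$decile_mean_errors == 0))
  expect_equal(perfect$max_decile_error, 0)

  flat <- prediction_metrics(y2, rep(mean(y2), 100))
  expect_equal(flat$r_squared, 0)

  # anti-predictor: R squared is negative and must not be clamped
  anti <- prediction_metrics(y2, 2 * mean(y2) - y2)
  expect_equal(anti$r_squared, -3, tolerance = 1e-12)

  expect_error(prediction_metrics(rep(1, 20), rnorm(20)), "variance")
  expect_error(prediction_metrics(y2, y2[-1]), "length")
})

test_that("decile errors localize miscalibration and average correctly", {
  yhat <- as.numeric(1:20)
  y <- yhat + c(rep(0, 18), 1, 1)   # top decile off by +1
  d <- decile_mean_errors(y, yhat)
  expect_equal(unname(d$errors), c(rep(0, 9), 1))
  expect_equal(d$max_error, 1)
  expect_false(d$collapsed)

  # weighted average of decile errors equals the overall mean residual
  set.seed(72)
  y3 <- rgamma(237, 3, 0.5)
  yhat3 <- y3 * exp(rnorm(237, 0, 0.3))
  d3 <- decile_mean_errors(y3, yhat3)
  expect_equal(sum(d3$errors * d3$n_per_group) / sum(d3$n_per_group),
               mean(y3 - yhat3), tolerance = 1e-10)

  # max error is signed, with the largest magnitude
  expect_equal(abs(d3$max_error), max(abs(d3$errors)))
  expect_true(d3$max_error %in% d3$errors)

  # all predictions tied: single collapsed group
  y4 <- rnorm(30, 10)
  d4 <- decile_mean_errors(y4, rep(2, 30))
  expect_true(d4$collapsed)
  expect_equal(unname(d4$errors), mean(y4) - 2)

  expect_error(decile_mean_errors(y4[1:5], y4[1:5]), "at least 10")
})
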