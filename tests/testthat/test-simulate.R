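test_that("the generator is deterministic and respects the DGP", {
  d1 <- simulate_shape_dgp(500, seed = 99)
  d2 <- simulate_shape_dgp(500, seed = 99)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$x, d2$x)
  d3 <- simulate_shape_dgp(500, seed = 100)
  expect_false(identical(d1$y, d3$y))

  expect_true(all(d1$y > 0))
  expect_true(all(d1$x >= 0 & d1$x <= 2))
  expect_equal(d1$design[, "x2"], d1$x^2)
  expect_equal(unname(d1$design[, "Const"]), rep(1, 500))
  expect_identical(d1$true_theta, c(2, 0.05, 1))
})

test_that("simulated outcomes match the quadrature mean oracle", {
  # E(Y) = (1/2) integral over (0,2) of exp(2x + 0.05 x^2 + 1) dx
  target <- integrate(function(x) exp(2 * x + 0.05 * x^2 + 1) / 2,
                      0, 2, rel.tol = 1e-10)$value
  d <- simulate_shape_dgp(200000, seed = 404)
  expect_lt(abs(mean(d$y) - target) / target, 0.01)

  # scale-parameter generator: mean alpha * beta(x)
  target2 <- integrate(function(x) exp(3) * exp(2 * x + 1) / 2,
                       0, 2, rel.tol = 1e-10)$value
  ds <- simulate_scale_dgp(200000, theta = c(2, 0, 1), log_alpha = 3,
                           seed = 405)
  expect_lt(abs(mean(ds$y) - target2) / target2, 0.01)
})

test_that("estimate summaries compute the documented statistics", {
  est <- cbind(a = c(1, 3), b = c(2, 2))
  ses <- cbind(a = c(0.5, 0.7), b = c(0.1, 0.3))
  s <- summarize_estimates(est, ses)
  expect_equal(s$mean, c(2, 2))
  expect_equal(s$sd, c(sqrt(2), 0))
  expect_equal(s$mean_se, c(0.6, 0.2))
  expect_equal(s$mcse_mean, s$sd / sqrt(2))
  # too few replicates for the normality machinery
  expect_true(all(is.na(s$p_joint)))

  # degenerate column: all estimates identical -> undefined moments
  # reported as NA, not an error
  est2 <- matrix(rep(1.5, 20), ncol = 2)
  s2 <- summarize_estimates(est2, est2 * 0.1)
  expect_equal(s2$sd, c(0, 0))
  expect_true(all(is.na(s2$p_skewness)))

  expect_error(summarize_estimates(est, ses[, 1, drop = FALSE]),
               "matching dimensions")

  # self-consistency on synthetic normal draws
  set.seed(55)
  big <- matrix(rnorm(10000, mean = 2, sd = 0.166), ncol = 1)
  s3 <- summarize_estimates(big, abs(big) * 0 + 0.166,
                            true_values = 2)
  expect_equal(s3$mean, 2, tolerance = 0.01)
  expect_equal(s3$sd, 0.166, tolerance = 0.01)
  expect_gt(s3$p_joint, 0.05)
  expect_equal(s3$pct_bias, 100 * (s3$mean - 2) / 2)
})

test_that("the Monte Carlo harness is reproducible and audit-friendly", {
  csv <- tempfile(fileext = ".csv")
  mc1 <- run_monte_carlo(10, n_obs = 300, seed = 17,
                         models = c("scale", "shape"),
                         replicate_path = csv)
  mc2 <- run_monte_carlo(10, n_obs = 300, seed = 17,
                         models = c("scale", "shape"))
  expect_identical(mc1$summary, mc2$summary)
  expect_identical(mc1$estimates, mc2$estimates)

  expect_equal(unname(mc1$n_converged + mc1$n_failed), c(10L, 10L))
  expect_true(file.exists(csv))
  reps <- read.csv(csv)
  expect_setequal(names(reps),
                  c("replicate", "model", "coefficient", "estimate",
                    "se", "converged"))
  expect_equal(nrow(reps), 10 * 2 * 3)

  # summaries carry Monte Carlo standard errors for tolerance-aware use
  expect_true(all(c("mcse_mean", "mcse_sd") %in% names(mc1$summary)))
  expect_true(all(mc1$summary$mcse_mean > 0))

  # per-model coefficient layout mirrors the design columns
  expect_equal(colnames(mc1$estimates$shape), c("x", "x2", "Const"))
})
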