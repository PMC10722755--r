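spec3 <- function(param) model_spec(param, c("x", "x2", "Const"))

test_that("intercept-only MLE reproduces the sample mean exactly", {
  set.seed(8)
  y <- rgamma(300, shape = 1.4, scale = 5)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "Const"))
  for (param in c("shape", "scale", "shape_scale")) {
    fit <- fit_gamma_regression(X, y, model_spec(param, "Const"))
    expect_true(fit$converged)
    # first-order condition in the constant parameter forces
    # alpha-hat * beta-hat = ybar
    expect_equal(unname(predict_mean(fit, X)), rep(mean(y), length(y)),
                 tolerance = 1e-8)
  }
})

test_that("shape model recovers the generating parameters at large n", {
  d <- simulate_shape_dgp(100000, seed = 42)
  fit <- fit_gamma_regression(d$design, d$y, spec3("shape"))
  expect_true(fit$converged)
  mcf <- mean_coefficients(fit)
  truth <- c(2, 0.05, 1)
  for (j in 1:3)
    expect_lt(abs(mcf$coefficients[j] - truth[j]),
              3 * mcf$standard_errors[j])
  aux_se <- fit$standard_errors["log_beta"]
  expect_lt(abs(fit$aux_log_constant - 3), 3 * aux_se)
})

test_that("scale-model estimates equal an independent gamma GLM fit", {
  # the scale-model score in theta is proportional to the log-link
  # gamma GLM quasi-score, so slopes must agree exactly and the GLM
  # intercept must equal the scale constant plus log alpha-hat
  for (s in 1:20) {
    d <- simulate_scale_dgp(400, theta = c(0.8, 0.1, 1.5), log_alpha = 1.2,
                            seed = 1000 + s)
    fit <- fit_gamma_regression(d$design, d$y, spec3("scale"))
    expect_true(fit$converged)
    df <- data.frame(y = d$y, x = d$x, x2 = d$x^2)
    g <- glm(y ~ x + x2, data = df, family = Gamma(link = "log"),
             control = glm.control(epsilon = 1e-13, maxit = 100))
    expect_equal(unname(fit$theta_scale[c("x", "x2")]),
                 unname(coef(g)[c("x", "x2")]), tolerance = 1e-6)
    expect_equal(unname(fit$theta_scale[["Const"]] + fit$aux_log_constant),
                 unname(coef(g)[["(Intercept)"]]), tolerance = 1e-6)
  }
})

test_that("the shape/scale model nests both single-parameter fits", {
  for (s in 1:5) {
    d <- simulate_shape_dgp(500, seed = 200 + s)
    ll <- vapply(c("shape", "scale", "shape_scale"), function(param)
      fit_gamma_regression(d$design, d$y, spec3(param))$loglik,
      numeric(1))
    expect_gte(ll[["shape_scale"]], ll[["shape"]] - 1e-6)
    expect_gte(ll[["shape_scale"]], ll[["scale"]] - 1e-6)
  }
})

test_that("predictions follow the fitted mean structure", {
  d <- simulate_shape_dgp(800, seed = 77)
  fit_sh <- fit_gamma_regression(d$design, d$y, spec3("shape"))
  fit_sc <- fit_gamma_regression(d$design, d$y, spec3("scale"))
  mu_sh <- predict_mean(fit_sh, d$design)
  expect_true(all(mu_sh > 0))
  expect_equal(mu_sh,
               exp(drop(d$design %*% fit_sh$theta_shape) +
                     fit_sh$aux_log_constant))
  # different variance specifications weight observations differently,
  # so fits to heteroskedastic data disagree
  expect_gt(max(abs(mu_sh - predict_mean(fit_sc, d$design))), 1e-4)
  expect_error(predict_mean(fit_sh, d$design[, 1:2]), "columns")
  # S3 interface agrees
  expect_equal(predict(fit_sh, d$design), mu_sh)
})

test_that("degenerate fitting inputs are rejected or flagged", {
  d <- simulate_shape_dgp(50, seed = 9)
  Xdef <- cbind(d$design, dup = d$design[, "x"])
  expect_error(
    fit_gamma_regression(Xdef, d$y,
                         model_spec("shape", colnames(Xdef))),
    "rank deficient")
  expect_error(fit_gamma_regression(d$design, -d$y, spec3("shape")),
               "lower bound")
  # starved of iterations the fit reports non-convergence, no error
  slow <- fit_gamma_regression(d$design, d$y, spec3("shape"),
                               start = c(0, 0, 0, 8),
                               control = list(maxit = 1L))
  expect_false(slow$converged)
})

test_that("single-coefficient Wald test equals the squared z statistic", {
  d <- simulate_shape_dgp(400, seed = 33)
  X <- d$design[, c("x", "Const")]
  fit <- fit_gamma_regression(X, d$y, model_spec("shape_scale",
                                                 c("x", "Const")))
  for (block in c("shape", "scale")) {
    w <- wald_joint_test(fit, block)
    idx <- if (block == "shape") "shape.x" else "scale.x"
    z2 <- (coef(fit)[idx] / fit$standard_errors[idx])^2
    expect_equal(w$statistic, unname(z2), tolerance = 1e-10)
    expect_equal(w$df, 1)
    expect_equal(w$p_value, pchisq(w$statistic, 1, lower.tail = FALSE))
  }
  fit_single <- fit_gamma_regression(X, d$y, model_spec("shape",
                                                        c("x", "Const")))
  expect_error(wald_joint_test(fit_single), "shape_scale")
})

test_that("joint Wald tests separate the active from the inactive block", {
  # data generated with covariates acting on the shape parameter only:
  # the shape-block test should reject essentially always, the
  # scale-block test at about its nominal 5% level
  reps <- 200
  rej <- matrix(NA, reps, 2, dimnames = list(NULL, c("shape", "scale")))
  set.seed(14)
  seeds <- sample.int(1e7, reps)
  for (i in seq_len(reps)) {
    d <- simulate_shape_dgp(1000, seed = seeds[i])
    fit <- tryCatch(
      fit_gamma_regression(d$design, d$y, spec3("shape_scale")),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    rej[i, "shape"] <- wald_joint_test(fit, "shape")$p_value < 0.05
    rej[i, "scale"] <- wald_joint_test(fit, "scale")$p_value < 0.05
  }
  ok <- stats::complete.cases(rej)
  expect_gt(mean(ok), 0.98)
  expect_gt(mean(rej[ok, "shape"]), 0.99)
  # 3-sigma binomial band around 5% at ~200 replicates
  expect_lt(abs(mean(rej[ok, "scale"]) - 0.05),
            3 * sqrt(0.05 * 0.95 / sum(ok)) + 1e-9)
})

test_that("mean-equation reparameterization is exact", {
  d <- simulate_shape_dgp(600, seed = 55)
  for (param in c("shape", "scale", "shape_scale")) {
    fit <- fit_gamma_regression(d$design, d$y, spec3(param))
    mcf <- mean_coefficients(fit)
    # predictions computed from the mean-equation coefficients agree
    expect_equal(predict_mean(fit, d$design),
                 exp(drop(d$design %*% mcf$coefficients)),
                 tolerance = 1e-10)
    expect_equal(mcf$standard_errors,
                 sqrt(diag(mcf$covariance)), ignore_attr = TRUE)
  }
})
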