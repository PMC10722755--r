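#' D'Agostino skewness/kurtosis omnibus normality test
#'
#' Moment-based sample skewness \eqn{\sqrt{b_1} = m_3/m_2^{3/2}} and
#' kurtosis \eqn{b_2 = m_4/m_2^2} (normal reference 3), each transformed
#' to an approximately standard-normal statistic — the
#' D'Agostino--Belanger--D'Agostino (1990) transformation for skewness
#' and the Anscombe--Glynn transformation for kurtosis — and combined
#' into the omnibus statistic \eqn{K^2 = Z_1^2 + Z_2^2}, referred to a
#' chi-square with 2 degrees of freedom. At the sample sizes this
#' package works with (hundreds to tens of thousands) the small-sample
#' empirical corrections found in some software are numerically
#' irrelevant and are not applied.
#'
#' @param samples numeric vector, at least 8 observations (the kurtosis
#'   transformation is unreliable below that).
#' @return Object of class \code{"normality_summary"}: list with
#'   \code{skewness}, \code{kurtosis}, \code{z_skewness},
#'   \code{z_kurtosis}, \code{p_skewness} (test of skewness 0),
#'   \code{p_kurtosis} (test of kurtosis 3), \code{statistic}
#'   (\eqn{K^2}), \code{p_joint}, \code{n}.
#' @examples
#' set.seed(1)
#' skewness_kurtosis_test(rnorm(500))$p_joint
#' skewness_kurtosis_test(rexp(500))$p_joint   # strong right skew
#' @export
skewness_kurtosis_test <- function(samples) {
  x <- as.numeric(samples)
  if (anyNA(x)) stop("missing values in 'samples'", call. = FALSE)
  n <- length(x)
  if (n < 8L) stop("need at least 8 observations", call. = FALSE)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0)
    stop("constant input: sample moments are undefined", call. = FALSE)
  b1 <- mean(d^3) / m2^1.5
  b2 <- mean(d^4) / m2^2

  # skewness: D'Agostino, Belanger & D'Agostino (1990)
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  a <- sqrt(2 / (W2 - 1))
  Z1 <- delta * asinh(Y / a)

  # kurtosis: Anscombe & Glynn transformation
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Z1^2 + Z2^2
  structure(list(
    skewness = b1, kurtosis = b2,
    z_skewness = Z1, z_kurtosis = Z2,
    p_skewness = 2 * stats::pnorm(-abs(Z1)),
    p_kurtosis = 2 * stats::pnorm(-abs(Z2)),
    statistic = K2,
    p_joint = stats::pchisq(K2, df = 2, lower.tail = FALSE),
    n = n), class = "normality_summary")
}

#' @export
print.normality_summary <- function(x, ...) {
  cat(sprintf("Skewness %.4f (p = %.4g), kurtosis %.4f (p = %.4g)\n",
              x$skewness, x$p_skewness, x$kurtosis, x$p_kurtosis))
  cat(sprintf("Joint K^2 = %.4f on 2 df, p = %.4g (n = %d)\n",
              x$statistic, x$p_joint, x$n))
  invisible(x)
}

#' Modified Park test of the variance power
#'
#' Estimates the power \eqn{\lambda} in
#' \eqn{V(Y \mid x) \propto E(Y \mid x)^\lambda} by a log-link GLM of
#' squared raw residuals \eqn{(y - \hat y)^2} on \eqn{\log \hat y}
#' (Manning--Mullahy construction), using the gamma family by default;
#' an OLS-on-logs variant is available for sensitivity. Wald tests are
#' reported against \eqn{\lambda \in \{0, 1, 2, 3\}}.
#'
#' \eqn{\lambda = 2} is the moment condition of the standard gamma scale
#' specification; \eqn{\lambda = 1} (variance directly proportional to
#' the mean) is the moment condition of the shape specification.
#' Rejecting \eqn{\lambda = 2} therefore does not rule out a gamma
#' distribution — the covariates may act through the shape parameter.
#'
#' @param y positive outcome vector.
#' @param yhat predicted conditional means, strictly positive,
#'   same length as \code{y}.
#' @param method \code{"glm"} (gamma family, log link; default) or
#'   \code{"ols"} (least squares of \eqn{\log(y - \hat y)^2} on
#'   \eqn{\log\hat y}, dropping exact zeros).
#' @return Object of class \code{"park_test"}: list with
#'   \code{lambda_hat}, \code{se_lambda}, \code{p_vs} (named p-values of
#'   the Wald tests of \eqn{\lambda} = 0, 1, 2, 3), \code{method},
#'   \code{n}.
#' @export
modified_park_test <- function(y, yhat, method = c("glm", "ols")) {
  method <- match.arg(method)
  if (length(y) != length(yhat))
    stop("'y' and 'yhat' must have the same length", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stop("non-finite values in inputs", call. = FALSE)
  if (any(yhat <= 0))
    stop("all predicted means must be strictly positive", call. = FALSE)
  r2 <- (y - yhat)^2
  lx <- log(yhat)
  if (method == "glm") {
    fit <- suppressWarnings(stats::glm(
      r2 ~ lx, family = stats::Gamma(link = "log"),
      start = c(mean(log(pmax(r2, min(r2[r2 > 0])))), 1),
      control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
    sm <- summary(fit)
    lambda <- unname(stats::coef(fit)[2L])
    se <- sm$coefficients[2L, 2L]
  } else {
    keep <- r2 > 0
    fit <- stats::lm(log(r2[keep]) ~ lx[keep])
    sm <- summary(fit)
    lambda <- unname(stats::coef(fit)[2L])
    se <- sm$coefficients[2L, 2L]
  }
  lam0 <- c(0, 1, 2, 3)
  z <- (lambda - lam0) / se
  p <- 2 * stats::pnorm(-abs(z))
  names(p) <- paste0("lambda=", lam0)
  structure(list(lambda_hat = lambda, se_lambda = se, p_vs = p,
                 method = method, n = length(y)),
            class = "park_test")
}

#' @export
print.park_test <- function(x, ...) {
  cat(sprintf("Modified Park test (%s): lambda = %.4f (SE %.4f)\n",
              x$method, x$lambda_hat, x$se_lambda))
  for (nm in names(x$p_vs))
    cat(sprintf("  H0 %s: p = %.4g\n", nm, x$p_vs[nm]))
  invisible(x)
}

#' Within-sample prediction criteria
#'
#' The three criteria used to compare fitted cost models within sample:
#' \eqn{R^2 = 1 - \mathrm{Var}(y - \hat y)/\mathrm{Var}(y)} (population
#' variances; may be negative when the regression function misses the
#' true conditional expectation — never clamped), root mean squared
#' error, and the mean residual \eqn{y - \hat y} within each decile of
#' predicted values together with the signed decile error of largest
#' magnitude.
#'
#' @param y outcome vector.
#' @param yhat predicted means, same length, at least 10 observations
#'   for the decile errors.
#' @return Object of class \code{"prediction_metrics"}: list with
#'   \code{r_squared}, \code{rmse}, \code{decile_mean_errors} (length
#'   10, or fewer when ties collapse groups), \code{max_decile_error},
#'   \code{decile_n} (group sizes), \code{collapsed} (flag: quantile
#'   ties merged groups), \code{n}.
#' @examples
#' y <- c(1, 2, 3, 4); yhat <- c(2, 2, 2, 4)
#' m <- prediction_metrics(y, yhat)
#' m$rmse  # sqrt(2/4)
#' @export
prediction_metrics <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("'y' and 'yhat' must have the same length", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stop("non-finite values in inputs", call. = FALSE)
  n <- length(y)
  res <- y - yhat
  pvar <- function(v) mean((v - mean(v))^2)  # population denominator
  vy <- pvar(y)
  if (vy == 0)
    stop("zero outcome variance: R-squared undefined", call. = FALSE)
  r2 <- 1 - pvar(res) / vy
  rmse <- sqrt(mean(res^2))
  dec <- if (n >= 10L) decile_mean_errors(y, yhat) else
    list(errors = NA_real_, max_error = NA_real_, n_per_group = NA,
         collapsed = NA)
  structure(list(r_squared = r2, rmse = rmse,
                 decile_mean_errors = dec$errors,
                 max_decile_error = dec$max_error,
                 decile_n = dec$n_per_group,
                 collapsed = dec$collapsed, n = n),
            class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("R-squared %.4f, RMSE %.4f (n = %d)\n",
              x$r_squared, x$rmse, x$n))
  if (!all(is.na(x$decile_mean_errors))) {
    cat("Decile mean residuals:\n")
    print(round(x$decile_mean_errors, 4))
    cat(sprintf("Max decile error (signed): %.4f\n", x$max_decile_error))
  }
  invisible(x)
}

#' Mean residuals by decile of predicted values
#'
#' Partitions observations into ten groups at the sample quantiles of
#' \code{yhat} (probabilities 0.1, ..., 0.9; left-open/right-closed
#' intervals, boundary ties assigned to the lower group) and averages
#' the raw residuals \eqn{y - \hat y} within each. The reported maximum
#' is the \emph{signed} group mean of largest absolute magnitude. When
#' heavy ties make some quantiles coincide, the collapsed (fewer than
#' ten) distinct groups are reported and flagged.
#'
#' @inheritParams prediction_metrics
#' @return List with \code{errors} (named vector of group mean
#'   residuals), \code{max_error} (signed, largest magnitude),
#'   \code{n_per_group}, \code{collapsed} (logical).
#' @export
decile_mean_errors <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("'y' and 'yhat' must have the same length", call. = FALSE)
  n <- length(y)
  if (n < 10L)
    stop("need at least 10 observations for decile errors",
         call. = FALSE)
  qs <- stats::quantile(yhat, probs = seq(0.1, 0.9, by = 0.1),
                        names = FALSE)
  breaks <- unique(c(-Inf, qs, Inf))
  collapsed <- length(breaks) < 11L
  g <- cut(yhat, breaks = breaks, right = TRUE, labels = FALSE)
  res <- y - yhat
  errors <- as.numeric(tapply(res, g, mean))
  sizes <- as.integer(tapply(res, g, length))
  ng <- length(errors)
  names(errors) <- paste0("D", seq_len(ng))
  max_error <- errors[which.max(abs(errors))]
  list(errors = errors, max_error = unname(max_error),
       n_per_group = sizes, collapsed = collapsed)
}
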