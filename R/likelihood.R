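# Negative log-likelihood, gradient and Hessian for the three gamma
# regression parameterizations. Parameter packing convention:
#   shape:       c(theta_shape [k], aux = log beta)
#   scale:       c(theta_scale [k], aux = log alpha)
#   shape_scale: c(theta_shape [k], theta_scale [k])
# All auxiliaries live on the log scale so positivity needs no
# constraints. The shift L is a fixed constant, never estimated.

unpack_params <- function(par, spec, k) {
  switch(spec$parameterization,
    shape = list(theta_shape = par[seq_len(k)], aux = par[k + 1L]),
    scale = list(theta_scale = par[seq_len(k)], aux = par[k + 1L]),
    shape_scale = list(theta_shape = par[seq_len(k)],
                       theta_scale = par[k + seq_len(k)]))
}

#' Negative log-likelihood of a gamma regression
#'
#' Evaluates the negative log-likelihood and its exact analytic gradient
#' for a packed parameter vector. Packing is \code{c(theta, aux)} for the
#' single-parameter models — \code{theta} the coefficients on the varied
#' parameter's log scale, \code{aux} the log of the constant parameter —
#' and \code{c(theta_shape, theta_scale)} for \code{"shape_scale"}.
#'
#' Mainly of interest for testing and for custom optimization; model
#' fitting goes through \code{\link{fit_gamma_regression}}.
#'
#' @param par packed numeric parameter vector (see Details).
#' @param X design matrix, intercept as last column.
#' @param y positive outcome vector (strictly greater than
#'   \code{lower_bound}).
#' @param spec a \code{\link{model_spec}}.
#' @param lower_bound fixed support lower bound \eqn{L} (default 0).
#' @return List with components \code{value} (the negative
#'   log-likelihood) and \code{gradient} (its analytic gradient, same
#'   length as \code{par}).
#' @export
negative_loglik <- function(par, X, y, spec, lower_bound = 0) {
  X <- check_design(X, y, spec, lower_bound)
  k <- ncol(X)
  if (length(par) != n_packed(spec, k))
    stop(sprintf("packed parameter vector has length %d, expected %d",
                 length(par), n_packed(spec, k)), call. = FALSE)
  nll_parts(par, X, y, spec, lower_bound, hessian = FALSE)[c("value",
                                                             "gradient")]
}

# Core computation. Returns value, gradient and (optionally) Hessian of
# the NEGATIVE log-likelihood. No input validation: hot path.
nll_parts <- function(par, X, y, spec, lower_bound = 0, hessian = TRUE) {
  k <- ncol(X)
  u <- y - lower_bound
  z <- log(u)
  n <- length(y)

  if (spec$parameterization == "shape") {
    theta <- par[seq_len(k)]; cc <- par[k + 1L]
    eta <- drop(X %*% theta)
    alpha <- exp(eta)
    ll <- sum(-lgamma(alpha) - alpha * cc + (alpha - 1) * z) -
      exp(-cc) * sum(u)
    w <- z - cc - digamma(alpha)
    g_theta <- drop(crossprod(X, alpha * w))
    g_c <- -sum(alpha) + exp(-cc) * sum(u)
    grad <- c(g_theta, g_c)
    out <- list(value = -ll, gradient = -unname(grad))
    if (hessian) {
      d <- alpha * w - alpha^2 * trigamma(alpha)
      H <- matrix(0, k + 1L, k + 1L)
      H[seq_len(k), seq_len(k)] <- crossprod(X, X * d)
      H[seq_len(k), k + 1L] <- H[k + 1L, seq_len(k)] <-
        -drop(crossprod(X, alpha))
      H[k + 1L, k + 1L] <- -exp(-cc) * sum(u)
      out$hessian <- -H
    }
  } else if (spec$parameterization == "scale") {
    theta <- par[seq_len(k)]; aa <- par[k + 1L]
    eta <- drop(X %*% theta)
    alpha <- exp(aa)
    r <- u * exp(-eta)
    ll <- -n * lgamma(alpha) - alpha * sum(eta) + (alpha - 1) * sum(z) -
      sum(r)
    g_theta <- drop(crossprod(X, r - alpha))
    g_a <- alpha * sum(z - eta - digamma(alpha))
    grad <- c(g_theta, g_a)
    out <- list(value = -ll, gradient = -unname(grad))
    if (hessian) {
      H <- matrix(0, k + 1L, k + 1L)
      H[seq_len(k), seq_len(k)] <- -crossprod(X, X * r)
      H[seq_len(k), k + 1L] <- H[k + 1L, seq_len(k)] <-
        -alpha * colSums(X)
      H[k + 1L, k + 1L] <- g_a - n * alpha^2 * trigamma(alpha)
      out$hessian <- -H
    }
  } else {
    theta_s <- par[seq_len(k)]; theta_b <- par[k + seq_len(k)]
    s <- drop(X %*% theta_s)
    b <- drop(X %*% theta_b)
    alpha <- exp(s)
    r <- u * exp(-b)
    ll <- sum(-lgamma(alpha) - alpha * b + (alpha - 1) * z - r)
    w <- z - b - digamma(alpha)
    g_s <- drop(crossprod(X, alpha * w))
    g_b <- drop(crossprod(X, r - alpha))
    grad <- c(g_s, g_b)
    out <- list(value = -ll, gradient = -unname(grad))
    if (hessian) {
      idx1 <- seq_len(k); idx2 <- k + idx1
      H <- matrix(0, 2L * k, 2L * k)
      H[idx1, idx1] <- crossprod(X, X * (alpha * w -
                                         alpha^2 * trigamma(alpha)))
      H[idx2, idx2] <- -crossprod(X, X * r)
      H[idx1, idx2] <- -crossprod(X, X * alpha)
      H[idx2, idx1] <- t(H[idx1, idx2])
      out$hessian <- -H
    }
  }
  out
}
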