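#' Specify a gamma regression parameterization
#'
#' Declares which gamma parameter(s) the covariates enter. All three
#' parameterizations use a natural-log link for the varied parameter(s),
#' so positivity is automatic:
#' \describe{
#'   \item{\code{"scale"}}{covariates enter \eqn{\log\beta}; the shape
#'     \eqn{\alpha} is a constant estimated alongside. Conditional
#'     variance is proportional to the squared conditional mean — the
#'     standard gamma GLM variance function.}
#'   \item{\code{"shape"}}{covariates enter \eqn{\log\alpha}; the scale
#'     \eqn{\beta} is a constant. Conditional variance is directly
#'     proportional to the conditional mean.}
#'   \item{\code{"shape_scale"}}{covariates enter both \eqn{\log\alpha}
#'     and \eqn{\log\beta}; nests the two single-parameter models.}
#' }
#'
#' The design matrix convention throughout the package is an explicit
#' intercept as the \emph{last} column.
#'
#' @param parameterization one of \code{"scale"}, \code{"shape"},
#'   \code{"shape_scale"}.
#' @param covariate_names character vector naming the design-matrix
#'   columns in order, intercept last. At least one column (the
#'   intercept) is required.
#' @return An object of class \code{"gamma_model_spec"}.
#' @examples
#' model_spec("shape", c("x", "x2", "Const"))
#' @export
model_spec <- function(parameterization = c("scale", "shape", "shape_scale"),
                       covariate_names = "Const") {
  parameterization <- match.arg(parameterization)
  covariate_names <- as.character(covariate_names)
  if (length(covariate_names) < 1L)
    stop("'covariate_names' must contain at least the intercept column",
         call. = FALSE)
  structure(list(parameterization = parameterization,
                 covariate_names = covariate_names,
                 link = "log"),
            class = "gamma_model_spec")
}

#' @export
print.gamma_model_spec <- function(x, ...) {
  cat(sprintf("Gamma regression spec: %s parameterization, log link\n",
              x$parameterization))
  cat("  design columns:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

# Number of packed parameters for a spec with k design columns:
# k coefficients + 1 auxiliary log-constant for the single-parameter
# models, 2k for shape_scale.
n_packed <- function(spec, k) {
  if (spec$parameterization == "shape_scale") 2L * k else k + 1L
}

# Validate design/outcome against a spec; returns column count.
check_design <- function(X, y, spec, lower_bound = 0) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X)))
    stop("design matrix contains missing or non-finite values",
         call. = FALSE)
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y)))
    stop("outcome contains missing or non-finite values", call. = FALSE)
  if (nrow(X) != length(y))
    stop("design matrix rows and outcome length differ", call. = FALSE)
  if (ncol(X) != length(spec$covariate_names))
    stop(sprintf("design has %d columns but spec declares %d covariates",
                 ncol(X), length(spec$covariate_names)), call. = FALSE)
  if (any(y <= lower_bound)) {
    bad <- which(y <= lower_bound)
    stop(sprintf(
      "outcome must be strictly greater than the support lower bound %g; violated at %d row(s), e.g. row %d (y = %g)",
      lower_bound, length(bad), bad[1L], y[bad[1L]]), call. = FALSE)
  }
  X
}
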