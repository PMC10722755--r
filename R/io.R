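#' Read a modelling dataset from CSV or TSV
#'
#' Reads a delimited file with a header row (the delimiter follows the
#' file extension: \code{.tsv}/\code{.tab} are tab-separated, anything
#' else comma-separated), selects the outcome and covariate columns by
#' name, and assembles the design matrix in the declared covariate order
#' with an explicit intercept column \code{Const} appended last. Missing
#' values and non-positive outcomes are rejected outright with the
#' offending row indices — silent dropping or imputation would change
#' the estimand.
#'
#' @param path path to the file.
#' @param outcome_name name of the strictly positive outcome column.
#' @param covariate_names character vector of numeric covariate column
#'   names (may be empty for an intercept-only design).
#' @param lower_bound support lower bound the outcome must exceed
#'   (default 0).
#' @return List with \code{y} (outcome vector), \code{design} (numeric
#'   matrix, intercept last), \code{covariate_names} (including
#'   \code{"Const"}).
#' @export
read_dataset <- function(path, outcome_name, covariate_names = character(),
                         lower_bound = 0) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  tab_ext <- grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)
  df <- if (tab_ext) utils::read.delim(path, check.names = FALSE)
    else utils::read.csv(path, check.names = FALSE)
  need <- c(outcome_name, covariate_names)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("column(s) not found in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  sel <- df[, need, drop = FALSE]
  na_rows <- which(!stats::complete.cases(sel))
  if (length(na_rows) > 0)
    stop(sprintf("missing values in rows: %s",
                 paste(utils::head(na_rows, 10), collapse = ", ")),
         call. = FALSE)
  y <- as.numeric(sel[[outcome_name]])
  bad <- which(y <= lower_bound)
  if (length(bad) > 0)
    stop(sprintf(
      "outcome '%s' must exceed %g (gamma support requirement); violated in row(s): %s",
      outcome_name, lower_bound,
      paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  if (length(covariate_names) > 0) {
    covs <- as.matrix(sel[, covariate_names, drop = FALSE])
    storage.mode(covs) <- "double"
    if (any(!is.finite(covs)))
      stop("non-numeric or non-finite covariate values", call. = FALSE)
    design <- cbind(covs, Const = 1)
  } else {
    design <- matrix(1, nrow = length(y), dimnames = list(NULL, "Const"))
  }
  list(y = y, design = design,
       covariate_names = c(covariate_names, "Const"))
}

# Serializable view of a fit: coefficients, SEs, covariance, loglik and
# convergence metadata, at full numeric precision.
fit_to_list <- function(fit) {
  list(parameterization = fit$spec$parameterization,
       covariate_names = fit$spec$covariate_names,
       link = fit$spec$link,
       coefficients = as.list(fit$coefficients),
       standard_errors = as.list(fit$standard_errors),
       aux_log_constant = fit$aux_log_constant,
       covariance = unname(fit$covariance),
       loglik = fit$loglik,
       converged = fit$converged,
       n_iterations = fit$n_iterations,
       n_observations = fit$n_observations,
       lower_bound = fit$lower_bound)
}

#' Write a fitted model to JSON
#'
#' Serializes coefficients, standard errors, the full covariance matrix,
#' the log-likelihood and convergence metadata at full precision.
#'
#' @param fit a \code{\link{gamma_fit}} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
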