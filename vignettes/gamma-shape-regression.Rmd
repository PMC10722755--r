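---
title: "Gamma regression through the shape parameter: models, estimation, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma regression through the shape parameter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammashape)
```

## The model

Positive, right-skewed outcomes — healthcare costs, lengths of stay,
waiting times — are routinely modelled with the two-parameter gamma
distribution, density

$$f(y) = \frac{1}{\Gamma(\alpha)\,\beta^{\alpha}}\,
  (y - L)^{\alpha - 1} e^{-(y - L)/\beta}, \qquad y > L,$$

with shape $\alpha > 0$, scale $\beta > 0$, and support lower bound $L$
(usually 0). Mean and variance are $E(Y) = L + \alpha\beta$ and
$V(Y) = \alpha\beta^2$. For a single distribution the variance can be
written equivalently as $(1/\alpha)\,(E(Y)-L)^2$ or as
$\beta\,(E(Y)-L)$; the package's moment functions verify both
identities.

The equivalence breaks once covariates enter. If covariates act on the
*scale* parameter ($\beta(x)$, $\alpha$ constant — the standard gamma
GLM specification), the conditional variance is proportional to the
*squared* conditional mean. If they act on the *shape* parameter
($\alpha(x)$, $\beta$ constant), the conditional variance is *directly
proportional* to the conditional mean. Both models have the same
log-link conditional-mean structure,
$E(Y \mid x) = e^{\gamma'x}$, and differ only in the variance function
— yet maximum likelihood under the wrong variance function yields
biased coefficients, understated standard errors, and skewed estimator
distributions. The package fits both, plus the `shape_scale` model in
which each parameter has its own coefficient vector and which nests the
other two.

## Parameterization and reporting

`fit_gamma_regression()` estimates, under a log link:

* `scale` — $\log\beta_i = \theta'x_i$ with $\log\alpha$ a free
  constant (`aux_log_constant`);
* `shape` — $\log\alpha_i = \theta'x_i$ with $\log\beta$ a free
  constant;
* `shape_scale` — $\log\alpha_i = \theta_s'x_i$,
  $\log\beta_i = \theta_b'x_i$.

Auxiliaries live on the log scale, so positivity never requires
constrained optimization. The design matrix carries an explicit
intercept as its *last* column.

Because the mean is the product of shape and scale, the coefficients of
$\log E(Y\mid x)$ are an exact linear transform of the packed
parameters: slopes are unchanged and the mean-equation constant is the
varied parameter's constant plus the auxiliary (for `shape_scale`, the
elementwise sum of the blocks). `mean_coefficients()` performs this
reparameterization, transforming the covariance exactly rather than by
delta-method approximation. The Monte Carlo harness summarizes
estimates on this mean-equation scale: it is the scale on which all
three parameterizations estimate the same quantity, so sampling
distributions are directly comparable across models. The raw blocks
(`theta_shape`, `theta_scale`, `aux_log_constant`) remain available on
every fit for variance-structure interpretation.

## Estimation

The log-likelihood, gradient, and Hessian are analytic for all three
parameterizations (the shape-block entries involve digamma and trigamma
terms). Fitting is Newton's method with

* a Cholesky factorization of the Hessian, ridged until positive
  definite so every step is a descent direction;
* Armijo backtracking with an acceptance tolerance placed just above
  the objective's floating-point noise floor (about $10^{-11}|\ell|$)
  — without this the search can stall one ulp away from the optimum;
* convergence when the gradient max-norm falls below $10^{-6}$ and the
  relative objective change below $10^{-10}$, with a 500-iteration cap;
* a BFGS restart (and Nelder–Mead as a last resort) if a Newton step
  fails, followed by Newton polishing.

Plain quasi-Newton iteration with only gradient information, and naive
Newton without the positive-definite safeguard, both proved fragile on
low-shape data ($\alpha < 1$), where the likelihood surface has
indefinite regions; the safeguarded Newton converged on every replicate
of the simulation study.

Starting values: least squares of $\log y$ on $X$ for the varied block,
recalibrated multiplicatively on the raw scale; the auxiliary
log-constant comes from the model's own variance relation applied to
crude residuals (variance $\propto$ mean for `shape`,
$\propto$ mean$^2$ for `scale`). An unconditional method-of-moments
start for the auxiliary was tried first and discarded: when the
conditional mean varies strongly, the unconditional variance is
dominated by mean variation and the start lands far from the optimum.
The `shape_scale` model starts from the better-fitting single-parameter
model, with the constant block seeded at $(0, \ldots, 0,
\text{aux})$.

Standard errors come from the inverse observed information (negative
Hessian at the optimum), the conventional default of general-purpose ML
software. Robust (sandwich) covariance is deliberately out of scope: in
the misspecified-model experiments the *divergence* between
information-based standard errors and the empirical sampling variation
is itself the phenomenon of interest.

Non-positive outcomes (at or below $L$) raise an error naming the
offending rows; silently dropping them would change the estimand. The
shift $L$ is accepted as a fixed, user-supplied constant and never
estimated.

## The synthetic data generator

`simulate_shape_dgp()` draws $x \sim U(0,2)$, builds the design
$(x, x^2, 1)$, and generates
$y \sim \text{Gamma}(\alpha(x) = e^{\gamma'x}/\beta,\ \beta)$ with
mean-equation coefficients $\gamma = (2, 0.05, 1)$ and $\beta = e^3$ by
default. These defaults are the package's reference study conditions:
the conditional mean spans roughly $e$ to $e^{5.2}$, the shape
parameter roughly $0.14$ to $3.3$, so the outcome is strongly
right-skewed with variance directly proportional to the mean — a
cost-like variable for which the covariate acts through the shape
parameter. A note on coordinates: defining the generator by its mean
equation (rather than by a free-standing shape equation) is what makes
the constant's generating value equal 1 on the reporting scale; the
implied log-shape equation is the same vector with $\log\beta$
subtracted from its constant.

`simulate_scale_dgp()` is the mirrored generator (covariates in
$\log\beta$, constant $\alpha$), used to study the reverse
misspecification and to exercise the Modified Park test at power 2.

What the generator does *not* emulate about real cost data: point mass
at or near zero, covariate correlation and discreteness, outcome
contamination and top-coding, and cluster structure. Passing the
simulation-based tests therefore demonstrates correctness of the
estimators and diagnostics under a clean gamma DGP, not robustness on
messy administrative data.

## The Monte Carlo harness

`run_monte_carlo()` repeats simulate-and-fit over a requested set of
parameterizations and summarizes each coefficient's sampling
distribution: mean, SD ($n-1$ denominator), mean estimated standard
error, and D'Agostino skewness/kurtosis diagnostics, each with its
Monte Carlo standard error (SD$/\sqrt{R}$ for means,
SD$\sqrt{1/(2(R-1))}$ for SDs), so comparisons against reference values
can be tolerance-aware.

A master seed draws one sub-seed per replicate up front, making runs
reproducible bit-for-bit and replicate $i$ independent of which models
are requested. Replicates whose fit does not converge are excluded and
counted, never imputed; because failures should be essentially absent
under the reference DGP, the harness aborts if more than 1% fail —
wholesale dropping would silently condition the summaries on easy
samples.

Problem sizes: the package's reference configuration is 10,000
replicates of $n = 1000$, which the test suite and the acceptance
script run in full (a few minutes with the analytic-Hessian Newton
fitter). For quick desk checks, a reduced `reps = 2000` run is the
documented preset; with $R = 2000$ the Monte Carlo standard errors
above are about $2.2\times$ wider, and pass/fail bands should be
widened accordingly.

## Diagnostics

**Normality of estimator distributions.** `skewness_kurtosis_test()`
implements the D'Agostino–Belanger–D'Agostino (1990) transformed
skewness test, the Anscombe–Glynn kurtosis test, and their omnibus
$K^2 = Z_1^2 + Z_2^2$ against $\chi^2_2$. Moment-based sample skewness
and raw kurtosis (normal reference 3) are used. Royston's empirical
small-sample correction, found in some software, is *not* applied: it
matters for $n \lesssim 100$, and the package applies the test to
Monte Carlo estimate vectors with $n$ in the thousands, where the
uncorrected and corrected forms agree to the printed digits. The
implementation is unit-tested against an independent implementation of
the same construction.

**Modified Park test.** `modified_park_test()` estimates $\lambda$ in
$V(Y\mid x) \propto E(Y\mid x)^\lambda$ by a gamma-family log-link GLM
of squared raw residuals on $\log \hat y$, with Wald tests of
$\lambda \in \{0, 1, 2, 3\}$; an OLS-on-logs variant is available
behind `method = "ols"` for sensitivity. $\lambda = 2$ is the moment
condition of the scale specification, $\lambda = 1$ of the shape
specification — so rejecting $\lambda = 2$ does not rule out a gamma
distribution, and if covariates act on both parameters no single power
holds and the test simply does not apply.

**Prediction criteria.** `prediction_metrics()` reports
$R^2 = 1 - \mathrm{Var}(y-\hat y)/\mathrm{Var}(y)$ (population
denominators in both terms; the convention cancels in the ratio),
RMSE, and mean residuals within deciles of predicted values, plus the
*signed* decile error of largest magnitude. $R^2$ may be negative —
the regression function then deviates from the true conditional
expectation more than a constant would — and is never clamped. Decile
groups are formed at the sample quantiles of $\hat y$ (probabilities
$0.1, \ldots, 0.9$), left-open/right-closed, boundary ties to the
lower group; if heavy ties make quantiles coincide, the collapsed
groups are reported and flagged rather than padded. Only within-sample
criteria are provided; cross-validated variants are out of scope.

## Numerical and degenerate-input choices

* Replicate-level results can be dumped as a long-format CSV
  (`replicate_path`) for audit.
* `summarize_estimates()` reports normality diagnostics as `NA` when a
  coefficient's estimates are constant (undefined moments) or fewer
  than 8 replicates are available, rather than erroring the whole
  summary.
* All `table1`/`simulate` artifacts embed the resolved configuration
  and master seed and contain no timestamps, so rerunning a recorded
  configuration reproduces them bit-for-bit.
* Missing values in input datasets are rejected with row indices; no
  imputation.

## Known limitations

Only the natural-log link is implemented; there is no censoring,
truncation, or two-part/hurdle structure for zero-heavy outcomes; no
robust covariance; no power-variance families beyond the three
parameterizations (a general variance-power gamma model would subsume
both specifications but is a different estimand). The `shape_scale`
model doubles the parameter count and, as with any such expansion, can
be fragile in small samples; its joint Wald tests
(`wald_joint_test()`) assume the gamma family and test only *which*
parameter the covariates enter.
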