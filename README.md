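# gammashape

Maximum-likelihood gamma regression for positive, right-skewed outcomes
— healthcare costs, lengths of stay, waiting times — under three
log-link parameterizations of *how* covariates enter the distribution,
with specification diagnostics and a Monte Carlo harness for comparing
the estimators' sampling distributions.

## The problem

A gamma variable has density
f(y) = y^(α−1) e^(−y/β) / (Γ(α) β^α) with shape α, scale β,
mean E(Y) = αβ and variance V(Y) = αβ². In a regression, covariates
must act through α, β, or both, and the choice fixes the variance
function:

| model | specification | conditional variance |
|---|---|---|
| `scale` | log β(x) = θ'x, α constant | (1/α) · E(Y\|x)² |
| `shape` | log α(x) = θ'x, β constant | β · E(Y\|x) |
| `shape_scale` | both vary | no single power of the mean |

All three share the same log-link conditional mean
E(Y|x) = exp(γ'x), so they are indistinguishable in the mean — but
maximum likelihood under the wrong variance function gives biased
coefficients, understated standard errors, and skewed estimator
distributions. The usual gamma GLM is the `scale` row; the `shape`
specification (variance *directly proportional* to the mean) is the
alternative this package makes routine, along with the tools for
telling the specifications apart: joint Wald tests on the
`shape_scale` fit, the Modified Park test of the variance power, and
within-sample prediction criteria (R², RMSE, decile mean residuals).

## Worked example

```r
library(gammashape)

# cost-like data: mean exp(2x + 0.05x^2 + 1), variance proportional to
# the mean (covariates act through the shape parameter)
d <- simulate_shape_dgp(2000, seed = 42)

fit <- fit_gamma_regression(d$design, d$y, "shape")
fit
#> Gamma regression (shape parameterization, log link)
#>   n = 2000, log-likelihood = -6722.9609, converged: TRUE (7 iterations)
#>             estimate std_error  z_value    p_value
#> shape.x      2.06294   0.11445  18.0253  1.233e-72
#> shape.x2     0.03182   0.04820   0.6603  5.091e-01
#> shape.Const -2.03219   0.05756 -35.3054 4.851e-273
#> log_beta     2.99645   0.03756  79.7824  0.000e+00

round(mean_coefficients(fit)$coefficients, 4)
#>      x     x2  Const
#> 2.0629 0.0318 0.9643
```

The coefficient blocks are reported on the varied parameter's log
scale (here log α, plus the estimated constant log β = 3.00);
`mean_coefficients()` rotates them exactly onto the log-mean scale,
where the generating values were (2, 0.05, 1).

```r
yhat <- predict_mean(fit, d$design)
prediction_metrics(d$y, yhat)
#> R-squared 0.7152, RMSE 29.4874 (n = 2000)
#> Decile mean residuals:
#>      D1      D2      D3      D4      D5      D6      D7      D8      D9     D10
#> -0.0597 -0.1313  0.6894 -0.5447  0.6224 -0.8883 -1.5281  0.7736  1.0035  0.0632
#> Max decile error (signed): -1.5281

modified_park_test(d$y, yhat)
#> Modified Park test (glm): lambda = 1.0354 (SE 0.0608)
#>   H0 lambda=0: p = 5.751e-65
#>   H0 lambda=1: p = 0.5601
#>   H0 lambda=2: p = 1.287e-56
#>   H0 lambda=3: p = 8.567e-229
```

The estimated variance power λ ≈ 1 retains the shape specification and
rejects the standard λ = 2 — evidence that rejecting the usual gamma
moment condition does not rule out a gamma distribution. Fitting both
parameter blocks and testing each one points the same way:

```r
both <- fit_gamma_regression(d$design, d$y, "shape_scale")
wald_joint_test(both, "shape")   # chi-square = 2043.29, df = 2, p ~ 0
wald_joint_test(both, "scale")   # chi-square = 1.40,    df = 2, p = 0.50
```

`run_monte_carlo()` wraps simulate-and-fit over many replicates and
summarizes each coefficient's sampling distribution (mean, SD, mean
estimated SE, skewness/kurtosis normality tests, Monte Carlo standard
errors). A command-line wrapper over the same functions lives in
`inst/cli/gammashape.R` with subcommands `fit`, `diagnose`,
`simulate`, and `table1`.

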