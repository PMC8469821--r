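# divtune

Robust divergence estimation with Hyvärinen-score selection of the
robustness tuning parameter.

## The problem

Outlier-contaminated data — common in biostatistics and epidemiological
modelling — break maximum likelihood. Robust divergences fix this: the
**density power divergence (DPD)**

$$D_\gamma(y_i;\theta) = \frac{1}{\gamma} f(y_i;\theta)^\gamma -
  \frac{1}{1+\gamma}\int f(t;\theta)^{1+\gamma}\,dt$$

and the **γ-divergence** (transformed additive form
$\gamma^{-1} f^\gamma / C_\gamma(\theta)$,
$C_\gamma = (\int f^{1+\gamma})^{\gamma/(1+\gamma)}$) downweight
low-density observations, with a tuning parameter γ trading robustness
(large γ) against efficiency (small γ; γ = 0 is maximum likelihood). The
practical obstacle is choosing γ: classical rules need pilot estimates
and closed-form asymptotic variances.

`divtune` selects γ with a criterion that needs neither. Treating
$\exp\{D_\gamma\}$ as an unnormalized model, the Hyvärinen score of its
marginal likelihood reduces asymptotically to

$$H_n(\gamma) = \frac{1}{n}\sum_{i=1}^n \left\{ 2 D_\gamma''(y_i;
  \hat\theta_\gamma) + D_\gamma'(y_i;\hat\theta_\gamma)^2 \right\},
  \qquad \gamma_{opt} = \arg\min_\gamma H_n(\gamma),$$

where the derivatives are with respect to the *observations* — cheap for
any parameter dimension, and available even for penalized estimators.

The package provides: normal, gamma and normal-linear-regression model
families with exact observation derivatives and closed-form power
integrals; DPD and γ-divergence M-estimation (BFGS with analytic
gradients, warm-started γ-grid paths); per-family closed-form $H_n$ plus
the generic assembly; a small-n exact marginal-likelihood score oracle; a
generic sandwich covariance with Wald intervals; ℓ1-penalized
γ-divergence regression with cross-validated λ; and a reproducible
Monte-Carlo contamination harness.

## Worked example

The packaged fixture is a synthetic stand-in for the classical
speed-of-light measurements: 66 normal-ish values with two gross negative
outliers.

```r
library(divtune)
d <- read_dataset(system.file("extdata", "synthetic_newcomb.csv",
                              package = "divtune"))
sel <- select_gamma("dpd", normal_family(), d, seq(0, 0.7, by = 0.01))
sel
#> H-score selection (dpd, family normal): gamma_opt = 0.08
#>   grid of 71 points on [0, 0.7]; H_n at optimum: -0.0731785
round(sel$fit_opt$params, 3)
#>     mu sigma2
#> 28.244 12.739
round(div_fit(div_spec("dpd", 0, normal_family()), d)$params, 3)
#>      mu  sigma2
#>  26.697 101.696
```

The criterion picks a small positive γ = 0.08: the robust fit discounts
the two outliers (variance 12.7 instead of the ML's outlier-inflated
101.7, mean pulled back up to 28.2) without sacrificing efficiency on the
clean bulk. On the actual classical data (`MASS::newcomb`) the same
search selects γ = 0.09. A shell entry point wraps the same functions:

```sh
exec/divtune select --data inst/extdata/synthetic_newcomb.csv \
  --family normal --gamma-grid 0:0.7:0.01 --out sel.json
```

Simulation studies follow the same pattern (`contamination_scenario()` +
`run_study()`); see the vignette (`vignettes/hscore-tuning.Rmd`) for the
model details, numerical choices and the harness design.

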