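---
title: "The power-modified Lindley distribution: model, inference and stress-strength reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The power-modified Lindley distribution: model, inference and stress-strength reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmlindley)
```

## The model

The modified Lindley (ML) distribution is a one-parameter lifetime law
whose cdf damps the polynomial term of the classical Lindley cdf by an
extra exponential factor:

$$G(t;\theta) = 1 - e^{-\theta t}\Big[1 + \frac{\theta t}{\theta+1}
  e^{-\theta t}\Big], \qquad t > 0 .$$

The power-modified Lindley (PML) distribution is the law of
$X = T^{1/\alpha}$ for $T \sim \mathrm{ML}(\theta)$. The extra shape
parameter $\alpha > 0$ buys the same flexibility the power Lindley buys
over the Lindley: increasing or decreasing, unimodal and bathtub-adjacent
hazard shapes, and tunable skewness and kurtosis. Its cdf and pdf are

$$F(x) = 1 - e^{-\theta x^\alpha}\Big[1 + \frac{\theta x^\alpha}{\theta+1}
  e^{-\theta x^\alpha}\Big], \qquad
  f(x) = \frac{\theta\alpha}{\theta+1} e^{-2\theta x^\alpha} x^{\alpha-1}
  \big[(1+\theta)e^{\theta x^\alpha} + 2\theta x^\alpha - 1\big].$$

`alpha` is dimensionless; `theta` carries the dimension
$[x]^{-\alpha}$, so small fitted `theta` values on data with large
magnitudes (hundreds, as in the jute-fibre strengths) are expected.

### Numerical design

Three choices matter for correctness at extreme arguments and are used
everywhere downstream:

* **Log-space density.** The bracket $(1+\theta)e^{\theta x^\alpha}$
  overflows for moderate $\theta x^\alpha$. The implementation divides
  the bracket through by $e^{\theta x^\alpha}$ and assembles the log
  density as $-u + \log\{1+\theta + (2u-1)e^{-u}\}$ with
  $u = \theta x^\alpha$; the damped term is set to its limit 0 once
  $u > 700$, where $e^{-u}$ underflows.
* **Quantiles by root bracketing in $u$.** No closed-form inverse exists
  (the cdf mixes $e^{-u}$ and $e^{-2u}$). Because the cdf depends on
  $x$ only through $u$, the inverse is found once in $u$ by geometric
  bracket expansion plus `uniroot` at tolerance `1e-14`, then mapped
  back through $x = (u/\theta)^{1/\alpha}$. Round-trip accuracy is
  checked to `1e-10` in the tests.
* **Non-regularised incomplete gammas.** All incomplete-moment formulas
  use $\Gamma(a,z)$ and its lower companion; R's regularised `pgamma` is
  rescaled by `gamma(a)`.

Moments have the closed form
$\mu'_r = \Gamma(r/\alpha+1)\,\theta^{-r/\alpha}
\big[1 + (r/\alpha)/(2^{r/\alpha+1}(1+\theta))\big]$; every closed-form
summary (incomplete moments, mean residual life, mean inactivity time,
mean deviations, Bonferroni/Lorenz curves, residual-life moments) is
tested against adaptive quadrature of the density itself, which we treat
as the authoritative arbiter wherever a printed formula and the integral
disagree. The mgf is evaluated by quadrature rather than by its series
expansion, whose radius of convergence is not characterised; the series
is kept as a small-$|t|$ cross-check. The integral converges for all
$t \le 0$, for all $t$ when $\alpha > 1$, and for $t < \theta$ when
$\alpha = 1$; other arguments are rejected rather than extrapolated.
`ppml(0, ...)` returns 0, but the density and hazard are not defined at
0 (the limit depends on $\alpha$) and deliberately raise an error there.

## Maximum likelihood

`fit_pml()` maximises the exact log-likelihood (including the
$(\alpha-1)\sum\log x_i$ Jacobian term) over
$(\log\alpha, \log\theta)$ — the log scale enforces positivity without
constrained optimisation. BFGS with the analytic score runs from five
deterministic moment-flavoured starts and each solution is polished by
Nelder–Mead; the best value wins. The likelihood surface is flat in
$\theta$ for small $\theta$, which is exactly the regime of the packaged
jute and bank datasets, so the multi-start plus polish is not paranoia:
single-start Newton-type iterations stall visibly away from the optimum
on these data. The `converged` flag additionally requires the score norm
at the reported optimum to be negligible, so a stalled fit is reported
as such rather than silently returned.

Standard errors invert the observed information (central-difference
Hessian of the negative log-likelihood at the optimum). The expected
Fisher information is never evaluated in closed form for this family, so
the observed-information route is an explicit approximation choice, and
Wald intervals $\hat\phi \pm z_{\gamma/2}\widehat{\mathrm{se}}$ are used
throughout.

Goodness of fit reports the classical (uncorrected) KS, Cramér–von Mises
and Anderson–Darling statistics; small-sample corrected variants sit
behind `corrected = TRUE` because published tables rarely state which
convention they used. The KS p-value uses the asymptotic Kolmogorov
distribution of $\sqrt{n}D$ even though parameters are estimated from
the same data — the conventional, calibration-invalid usage; treat it as
descriptive.

## Bayesian machinery

Independent gamma priors $\alpha \sim \mathrm{Ga}(w_1, q_1)$,
$\theta \sim \mathrm{Ga}(w_2, q_2)$ (rate convention, so the prior mean
is $w/q$ — required for the moment-matching equations to hold exactly).
For a single observed dataset the hyperparameters are elicited from $k$
nonparametric bootstrap resamples refit by maximum likelihood
(`k = 100` by default): the prior moments are matched to the replicate
mean and ($k-1$ denominator) variance. This makes the prior data-driven
and the whole analysis reproducible from one seed; it is the package's
resolution of an otherwise underdetermined "replicate estimates"
elicitation recipe.

The posterior kernel is assembled directly as log-likelihood plus log
prior. (A published closed-form kernel for this model carries an
$e^{-\alpha\sum\ln x_i}$ factor that contradicts the likelihood's
$\prod x_i^{\alpha-1}$ term; building the kernel from its two defining
pieces avoids inheriting that misprint.)

`mh_sample_pml()` runs a Gaussian random walk on
$(\log\alpha, \log\theta)$ with the change-of-variable Jacobian in the
acceptance ratio, so positivity never needs rejection handling.
Proposal scales adapt toward an acceptance rate near 0.3 during burn-in
only and are frozen afterwards, preserving detailed balance for the
retained draws. Defaults are 10,000 iterations with 2,000 burn-in.
Sampler correctness is tested against a conjugate
exponential-likelihood/gamma-prior target with a known posterior.

Point estimators from the draws $\{\omega_i\}$:

| loss | estimator | shape |
|------|-----------|-------|
| squared error (SELF) | posterior mean | — |
| LINEX | $-c^{-1}\ln E[e^{-c\Omega}]$ | `c` (± asymmetry), default ±1.5 |
| entropy | $(E[\Omega^{-b}])^{-1/b}$ | `b`, default ±1.5 |

Entropy with $b=-1$ reduces to the posterior mean; LINEX with $c>0$
sits below the mean and $c<0$ above (Jensen), both verified as
properties in the tests. HPD intervals use the sorted-draw shortest
window (Chen–Shao) with first-index tie-breaking.

## Stress-strength reliability

For strength $X \sim \mathrm{PML}(\alpha, \theta_1)$ and stress
$Y \sim \mathrm{PML}(\alpha, \theta_2)$ sharing the shape, the
substitution $t = x^\alpha$ reduces $R = P(Y<X) = \int F_Y f_X$ to the
$\alpha$-free base scale. Integrating the base cdf against the base pdf
term by term gives the closed form implemented in `ss_reliability()`
(see its help page), which matches adaptive quadrature to below
$10^{-10}$ over $(\theta_1, \theta_2) \in [0.01, 100]^2$ and returns
exactly $1/2$ at $\theta_1 = \theta_2$, as any i.i.d.-continuous pair
must. A legacy closed form that circulates with this model fails that
identity; `ss_reliability_printed()` transcribes it for diagnosis and
reproduction of historical tables, always warns, and is never used in
analysis code. Reported reliability values computed from it (including
one widely quoted bank-data value) are not reproducible by the validated
formula; the package treats the validated form as the truth everywhere,
including in the simulation engine.

`fit_ss_mle()` maximises the joint likelihood in
$(\log\alpha, \log\theta_1, \log\theta_2)$, initialised at the averaged
marginal shape and the marginal rates. The delta-method variance of
$\hat R$ is $B^\top I^{-1} B$ with
$B = (0, \partial R/\partial\theta_1, \partial R/\partial\theta_2)$:
the first component is identically zero because $R$ is free of
$\alpha$, and the rate derivatives are exact (symbolic differentiation
of the closed form, cross-checked against finite differences in the
tests). The CI for $R$ is clipped to $[0,1]$; the unclipped interval is
retained because coverage studies must not benefit from clipping.
`fit_ss_bayes()` runs the three-parameter chain and pushes every draw
through `ss_reliability()`, so the $R$ draws inherit the validated
formula.

## The Monte-Carlo engine

`sim_study_pml()` and `sim_study_ss()` generate samples by inverting the
cdf at uniform draws, apply the requested estimators, and report bias,
MSE and mean interval length (Wald for the MLE, HPD for the Bayesian
estimators) per cell, with replicate failures dropped, counted, and
flagged when they exceed 10% of a cell.

Problem sizes are the package's own defaults: `L = 500` replicates,
sample sizes $\{35, 70, 140\}$ (singles) and $(30,30)/(45,50)/(70,60)$
(pairs), LINEX and entropy shapes $\pm 1.5$, and, inside simulation
cells only, shortened chains (3,000 iterations, 1,000 burn-in) with
`k = 50` bootstrap elicitation per replicate. These lengths were chosen
once as the smallest at which the qualitative conclusions (precision
growing with $n$, near-nominal coverage, tight-prior Bayes beating the
MLE cell-wise) are stable across seeds; all are arguments, so larger
studies are one call away.

What the generator emulates — and what it does not: samples are exact
i.i.d. PML draws, so passing recovery and coverage tests demonstrates
the estimators against their own model assumptions only. Real lifetime
data bring censoring, ties from rounding (visible in the bank data),
covariates and model misspecification, none of which the engine
simulates; conclusions about robustness to any of these are out of
scope.

## Known limitations

* Published parameter tables for the datasets shipped with this package
  were evidently produced by an optimiser that stopped short of the
  maximum: at the printed values the log-likelihood is strictly below
  the optimum this package finds, and the score is far from zero
  (e.g. COVID data: printed $(3.7674, 0.0562)$ with
  $\ell = -20.764$ versus the maximiser $(3.7899, 0.0631)$ with
  $\ell = -20.348$; the same pattern holds on the jute and bank data,
  while published *power-Lindley* rows are reproduced to all printed
  digits). The package reports the true maximiser together with an
  honest `converged` flag rather than reproducing stalled estimates.
* The KS p-values are asymptotic and ignore parameter estimation.
* Unequal shapes ($\alpha_x \neq \alpha_y$) are out of scope for the
  stress-strength model: the closed form requires the common power.
* The hazard-shape taxonomy is not classified symbolically; plots are
  the intended tool.

## Session info

```{r}
sessionInfo()
```
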