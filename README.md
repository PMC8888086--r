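# pmlindley

Inference for the **power-modified Lindley (PML) distribution**, a
two-parameter lifetime model for strictly positive data, with a full
toolkit for reliability work: distributional properties, maximum
likelihood, Bayesian estimation under symmetric and asymmetric losses,
stress-strength reliability P(Y < X), goodness-of-fit comparison against
standard lifetime families, and a Monte-Carlo engine for benchmarking
the estimators. It is aimed at reliability engineers and biostatisticians
fitting skewed positive data — mortality rates, failure strengths,
waiting times — where the Lindley family's flexibility is wanted but a
power shape parameter is needed.

## The model

The PML law is the distribution of `T^(1/alpha)` where `T` follows the
one-parameter modified Lindley distribution. With shape `alpha > 0` and
scale `theta > 0`,

    F(x) = 1 - exp(-t)[1 + t exp(-t)/(theta + 1)],   t = theta * x^alpha,
    f(x) = theta*alpha/(theta+1) * exp(-2t) * x^(alpha-1) *
           [(1+theta)exp(t) + 2t - 1].

`alpha = 1` recovers the modified Lindley distribution. Moments have a
closed form through the gamma function; incomplete moments, mean residual
life, mean inactivity time, mean deviations and Bonferroni/Lorenz curves
are expressed through incomplete gamma functions. For strength
X ~ PML(alpha, theta1) and stress Y ~ PML(alpha, theta2) the reliability
R = P(Y < X) has an alpha-free closed form, validated in the test suite
against adaptive quadrature to 1e-10.

## Worked example

```r
library(pmlindley)

x <- pml_data("covid_moldova")     # 28 daily COVID-19 mortality rates
fit <- fit_pml(x)
fit
#> Maximum-likelihood fit: pml distribution
#> n = 28  logLik = -20.3476  converged: TRUE
#>       estimate     se  lower  upper
#> alpha   3.7899 0.5694 2.6739 4.9059
#> theta   0.0631 0.0302 0.0040 0.1222

gof_test(x, fitted_cdf(fit))
#> KS D = 0.1800 (p = 0.3247)  CvM = 0.1400  AD = 0.9805  [n = 28]
```

The shape estimate near 3.8 says the mortality rates need a strongly
increasing hazard; the KS distance of 0.18 on n = 28 (p ≈ 0.32) does not
reject the PML fit. Stress-strength analysis on the jute-fibre breaking
strengths (strength at 10 mm gauge, stress at 20 mm):

```r
fit_ss <- fit_ss_mle(pml_data("jute_gauge10"), pml_data("jute_gauge20"))
fit_ss
#> Stress-strength PML fit (n = 30 , m = 30 )
#>        estimate     se   lower  upper
#> alpha    0.9979 0.0987  0.8044 1.1913
#> theta1   0.0034 0.0021 -0.0007 0.0074
#> theta2   0.0037 0.0022 -0.0007 0.0081
#> R = P(Y < X) = 0.5305  (se 0.0703, 95% CI 0.3926-0.6683)
```

R ≈ 0.53 estimates the probability that a fibre survives the 20 mm-gauge
stress level, with a delta-method interval. Bayesian analysis with
bootstrap-elicited gamma priors, loss-based point estimates (squared
error, LINEX, entropy) and HPD intervals:

```r
bf <- bayes_fit_pml(x, n_iter = 10000, burn_in = 2000, seed = 20220222)
bf$estimates       # tibble: parameter x estimator, value, posterior sd
bf$hpd             # HPD intervals per parameter
```

A command-line wrapper lives at `inst/exec/pml`
(`pml fit --data covid_moldova`, `pml ss --x jute_gauge10 --y jute_gauge20`,
`pml simulate --alpha 2 --theta 1 --reps 100 --seed 1`, ...).

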