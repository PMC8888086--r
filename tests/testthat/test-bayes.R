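test_that("gamma-prior elicitation moment-matches replicate estimates", {
  pr <- elicit_gamma_priors(cbind(alpha = c(1, 2, 3)))
  expect_equal(unname(pr[[1]]), c(4, 2), tolerance = 1e-12)
  # prior mean and variance reproduce the replicate mean and variance
  set.seed(2)
  reps <- cbind(a = rgamma(25, 3, 2), t = rgamma(25, 5, 10))
  pr2 <- elicit_gamma_priors(reps)
  for (j in 1:2) {
    w <- pr2[[j]]["shape"]; q <- pr2[[j]]["rate"]
    expect_equal(unname(w / q), mean(reps[, j]), tolerance = 1e-12)
    expect_equal(unname(w / q^2), var(reps[, j]), tolerance = 1e-12)
  }
  expect_error(elicit_gamma_priors(cbind(c(2, 2, 2))), "variance")
  expect_error(elicit_gamma_priors(cbind(1)), "at least 2")
})

test_that("log posterior is loglik plus log prior up to a constant", {
  x <- pml_data("covid_moldova")
  priors <- list(c(shape = 2, rate = 1), c(shape = 3, rate = 4))
  lp <- function(a, t) pml_log_posterior(x, a, t, priors)
  manual <- function(a, t)
    pml_loglik(x, a, t) + dgamma(a, 2, 1, log = TRUE) +
      dgamma(t, 3, 4, log = TRUE)
  # differences between any two points are exact
  expect_equal(lp(3, 0.06) - lp(4, 0.02), manual(3, 0.06) - manual(4, 0.02),
               tolerance = 1e-10)
  # near-flat prior: posterior differences approach loglik differences
  flat <- list(c(shape = 1, rate = 1e-9), c(shape = 1, rate = 1e-9))
  d_post <- pml_log_posterior(x, 3, 0.06, flat) -
    pml_log_posterior(x, 4, 0.02, flat)
  d_ll <- pml_loglik(x, 3, 0.06) - pml_loglik(x, 4, 0.02)
  expect_equal(d_post, d_ll, tolerance = 1e-6)
  # increasing the theta prior rate strictly decreases the log posterior
  heavier <- list(priors[[1]], c(shape = 3, rate = 9))
  expect_lt(pml_log_posterior(x, 3, 0.06, heavier), lp(3, 0.06))
  expect_identical(pml_log_posterior(x, -1, 1, priors), -Inf)
})

test_that("the MH kernel targets a known conjugate posterior", {
  # exponential likelihood + gamma(3, 2) prior => gamma(3 + n, 2 + sum x)
  set.seed(13)
  xe <- rexp(40, rate = 1.5)
  shape_post <- 3 + 40
  rate_post <- 2 + sum(xe)
  logtarget <- function(p)
    sum(dexp(xe, p[1], log = TRUE)) + dgamma(p[1], 3, 2, log = TRUE)
  ch <- pmlindley:::.mh_chain(logtarget, init = 1.5, scales = 0.2,
                              n_iter = 55000, burn_in = 5000, seed = 99)
  m <- shape_post / rate_post
  v <- shape_post / rate_post^2
  mc_se <- sqrt(v / (50000 / 20))  # generous effective-sample allowance
  expect_lt(abs(mean(ch$draws) - m), 4 * mc_se)
  expect_lt(abs(var(ch$draws) - v) / v, 0.1)
})

test_that("PML chains are reproducible, positive and well tuned", {
  x <- pml_data("covid_moldova")
  priors <- list(c(shape = 1, rate = 0.01), c(shape = 1, rate = 0.01))
  ch1 <- mh_sample_pml(x, priors, n_iter = 1500, burn_in = 500, seed = 4)
  ch2 <- mh_sample_pml(x, priors, n_iter = 1500, burn_in = 500, seed = 4)
  expect_identical(ch1$draws, ch2$draws)
  expect_true(all(ch1$draws > 0))
  expect_equal(nrow(ch1$draws), 1000L)
  expect_gt(ch1$acceptance_rate, 0.15)
  expect_lt(ch1$acceptance_rate, 0.5)
})

test_that("posterior recovers simulated truth within posterior uncertainty", {
  set.seed(17)
  x <- qpml(runif(200), 2, 2)
  priors <- list(c(shape = 1, rate = 0.01), c(shape = 1, rate = 0.01))
  ch <- mh_sample_pml(x, priors, n_iter = 6000, burn_in = 1500, seed = 18)
  pm <- colMeans(ch$draws)
  psd <- apply(ch$draws, 2, sd)
  expect_lt(abs(pm["alpha"] - 2), 3 * psd["alpha"])
  expect_lt(abs(pm["theta"] - 2), 3 * psd["theta"])
})

test_that("loss estimators reproduce hand-computed values and identities", {
  d <- c(1, 2, 3)
  expect_equal(loss_estimate(d, "self"), 2)
  expect_equal(loss_estimate(d, "linex", c = 1),
               -log((exp(-1) + exp(-2) + exp(-3)) / 3), tolerance = 1e-12)
  expect_equal(loss_estimate(d, "entropy", b = 1), 18 / 11, tolerance = 1e-12)
  # entropy with b = -1 is the posterior mean
  expect_equal(loss_estimate(d, "entropy", b = -1),
               loss_estimate(d, "self"), tolerance = 1e-12)
  # degenerate draws: every loss returns the common value
  dd <- rep(0.7, 50)
  expect_equal(loss_estimate(dd, "self"), 0.7)
  expect_equal(loss_estimate(dd, "linex", c = 1.5), 0.7, tolerance = 1e-12)
  expect_equal(loss_estimate(dd, "entropy", b = 1.5), 0.7, tolerance = 1e-12)
  expect_error(loss_estimate(d, "linex", c = 0), "nonzero")
  expect_error(loss_estimate(c(-1, 2), "entropy", b = 1), "positive")
})

test_that("Jensen orderings hold on non-degenerate draw sets", {
  set.seed(23)
  for (rep in 1:20) {
    d <- rgamma(200, shape = runif(1, 0.5, 5), rate = runif(1, 0.5, 5))
    s <- loss_estimate(d, "self")
    expect_lt(loss_estimate(d, "linex", c = 1.5), s)
    expect_gt(loss_estimate(d, "linex", c = -1.5), s)
    # power-mean inequality: entropy estimate <= mean for b >= -1
    expect_lte(loss_estimate(d, "entropy", b = 1), s)
    expect_lte(loss_estimate(d, "entropy", b = -0.5), s)
  }
  # LINEX -> SELF as c -> 0
  d <- rgamma(500, 2, 1)
  expect_equal(loss_estimate(d, "linex", c = 1e-6),
               loss_estimate(d, "self"), tolerance = 1e-4)
})

test_that("HPD intervals follow the sorted-window construction", {
  h <- hpd_interval(1:100, level = 0.90)
  expect_identical(c(h$lower, h$upper), c(1L, 91L))
  # covers at least ceiling(level * A) draws
  set.seed(29)
  d <- rgamma(500, 3, 1)
  h2 <- hpd_interval(d, level = 0.95)
  expect_gte(sum(d >= h2$lower & d <= h2$upper), ceiling(0.95 * 500))
  # never wider than the equal-tailed interval at the same level
  eq <- quantile(d, c(0.025, 0.975), names = FALSE)
  expect_lte(h2$upper - h2$lower, eq[2] - eq[1] + 1e-12)
  # contains the sample mode of a unimodal draw set
  dens <- density(d)
  mode_hat <- dens$x[which.max(dens$y)]
  expect_true(h2$lower <= mode_hat && mode_hat <= h2$upper)
  expect_error(hpd_interval(1:5, level = 0.95), "too few")
})

test_that("the full Bayesian fit is deterministic and internally coherent", {
  x <- pml_data("covid_moldova")
  bf <- bayes_fit_pml(x, k = 25, n_iter = 2000, burn_in = 500, seed = 77)
  bf2 <- bayes_fit_pml(x, k = 25, n_iter = 2000, burn_in = 500, seed = 77)
  expect_identical(bf$estimates$value, bf2$estimates$value)
  # SELF estimates lie inside their own HPD intervals
  for (p in c("alpha", "theta")) {
    self <- bf$estimates$value[bf$estimates$parameter == p &
                                 bf$estimates$estimator == "self"]
    expect_true(bf$hpd[[p]]$lower <= self && self <= bf$hpd[[p]]$upper)
  }
  # near-zero LINEX shape recovers SELF
  d <- bf$chain$draws[, "alpha"]
  expect_equal(loss_estimate(d, "linex", c = 1e-6),
               loss_estimate(d, "self"), tolerance = 1e-4)
})
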