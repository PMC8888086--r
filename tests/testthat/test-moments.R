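test_that("raw moments match the quadrature oracle and known values", {
  expect_equal(pml_moment(2, 1, 0), 1)
  # Gamma(2) * (1 + 1/(2^2 * 2)) at (alpha=1, theta=1, r=1)
  expect_equal(pml_moment(1, 1, 1), 1.125, tolerance = 1e-12)
  # E[X^2] under alpha=2 equals E[T] of the base law
  expect_equal(pml_moment(2, 1, 2), 1.125, tolerance = 1e-12)
  for (i in seq_len(nrow(param_grid))) {
    a <- param_grid$alpha[i]; t <- param_grid$theta[i]
    for (r in c(0.5, 1, 2, 3.5)) {
      expect_equal(pml_moment(a, t, r), quad_moment(a, t, r),
                   tolerance = 1e-8)
    }
  }
})

test_that("central moments, skewness and kurtosis follow from raw moments", {
  expect_equal(pml_central_moment(2, 0.5, 1), 0, tolerance = 1e-12)
  m1 <- pml_moment(2, 0.5, 1); m2 <- pml_moment(2, 0.5, 2)
  expect_equal(pml_central_moment(2, 0.5, 2), m2 - m1^2, tolerance = 1e-12)
  # against standardised quadrature moments
  v <- pml_central_moment(1.5, 1, 2)
  m3 <- quad(function(x) (x - m_q(1.5, 1))^3 * dpml(x, 1.5, 1), 0, Inf)
  m4 <- quad(function(x) (x - m_q(1.5, 1))^4 * dpml(x, 1.5, 1), 0, Inf)
  expect_equal(pml_skewness(1.5, 1), m3 / v^1.5, tolerance = 1e-7)
  expect_equal(pml_kurtosis(1.5, 1), m4 / v^2, tolerance = 1e-7)
})

test_that("mgf agrees with quadrature where it converges and rejects elsewhere", {
  expect_identical(pml_mgf(2, 1, 0), 1)
  for (tt in c(-1, -0.2, 0.3)) {
    expect_equal(pml_mgf(2, 1, tt),
                 quad(function(x) exp(tt * x) * dpml(x, 2, 1), 0, Inf),
                 tolerance = 1e-6)
  }
  # small-|t| series cross-check: sum_r t^r mu'_r / r!
  tt <- 0.05
  ser <- sum(vapply(0:30, function(r)
    tt^r / factorial(r) * pml_moment(2, 1, r), numeric(1)))
  expect_equal(pml_mgf(2, 1, tt), ser, tolerance = 1e-8)
  expect_error(pml_mgf(0.5, 1, 0.1), "diverges")   # heavy tail for alpha < 1
  expect_error(pml_mgf(1, 1, 1.5), "diverges")     # t >= theta at alpha = 1
})

test_that("incomplete moments match quadrature and add up", {
  cases <- list(c(1, 1, 1, 1), c(2, 0.5, 1, 1), c(0.5, 2, 2, 0.4),
                c(2, 1, 1.5, 0.7))
  for (cs in cases) {
    a <- cs[1]; t <- cs[2]; s <- cs[3]; tt <- cs[4]
    up <- pml_upper_inc_moment(a, t, s, tt)
    lo <- pml_lower_inc_moment(a, t, s, tt)
    expect_equal(up, quad_moment(a, t, s, lower = tt), tolerance = 1e-8)
    expect_equal(lo, quad_moment(a, t, s, upper = tt), tolerance = 1e-8)
    expect_equal(lo + up, pml_moment(a, t, s), tolerance = 1e-10)
  }
  expect_equal(pml_upper_inc_moment(2, 1, 1.5, 0), pml_moment(2, 1, 1.5),
               tolerance = 1e-12)
  # monotone nonincreasing in the truncation point
  ts <- seq(0, 3, by = 0.25)
  vals <- vapply(ts, function(tt) pml_upper_inc_moment(1, 1, 1, tt),
                 numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("mean residual life and mean inactivity time match conditional-expectation quadrature", {
  expect_equal(pml_mrl(1, 1, 0), pml_moment(1, 1, 1), tolerance = 1e-10)
  # E[X - 1 | X > 1] at (alpha=1, theta=1)
  surv <- 1 - ppml(1, 1, 1)
  oracle <- quad(function(x) (x - 1) * dpml(x, 1, 1), 1, Inf) / surv
  expect_equal(pml_mrl(1, 1, 1), oracle, tolerance = 1e-8)
  # E[2 - X | X < 2]
  oracle2 <- quad(function(x) (2 - x) * dpml(x, 1, 1), 0, 2) / ppml(2, 1, 1)
  expect_equal(pml_mit(1, 1, 2), oracle2, tolerance = 1e-8)
  ts <- seq(0.1, 5, by = 0.35)
  expect_true(all(vapply(ts, function(tt) pml_mrl(2, 0.5, tt), numeric(1)) >= 0))
  mits <- vapply(ts, function(tt) pml_mit(2, 0.5, tt), numeric(1))
  expect_true(all(mits >= 0 & mits <= ts))
  # MIT vanishes as t -> 0+
  expect_lt(pml_mit(2, 0.5, 1e-4), 1e-4)
})

test_that("mean deviations match E|X - c| quadrature; median beats mean", {
  for (ab in list(c(2, 1), c(1, 1), c(0.5, 2))) {
    a <- ab[1]; t <- ab[2]
    mu <- pml_moment(a, t, 1)
    med <- qpml(0.5, a, t)
    dm <- quad(function(x) abs(x - mu) * dpml(x, a, t), 0, Inf)
    dM <- quad(function(x) abs(x - med) * dpml(x, a, t), 0, Inf)
    expect_equal(pml_mean_deviation(a, t, "mean"), dm, tolerance = 1e-7)
    expect_equal(pml_mean_deviation(a, t, "median"), dM, tolerance = 1e-7)
    expect_gte(pml_mean_deviation(a, t, "mean"), 0)
    # the median minimises mean absolute deviation
    expect_lte(pml_mean_deviation(a, t, "median"),
               pml_mean_deviation(a, t, "mean") + 1e-12)
  }
})

test_that("Lorenz and Bonferroni curves are consistent and well behaved", {
  a <- 2; t <- 1
  mu <- pml_moment(a, t, 1)
  q5 <- qpml(0.5, a, t)
  oracle <- quad(function(x) x * dpml(x, a, t), 0, q5) / mu
  expect_equal(pml_lorenz(a, t, 0.5), oracle, tolerance = 1e-8)
  ps <- seq(0.05, 0.95, by = 0.05)
  L <- vapply(ps, function(p) pml_lorenz(a, t, p), numeric(1))
  B <- vapply(ps, function(p) pml_bonferroni(a, t, p), numeric(1))
  expect_equal(L, ps * B, tolerance = 1e-12)
  expect_true(all(diff(L) >= 0))
  expect_true(all(L <= ps + 1e-12))
  # convexity on the grid
  expect_true(all(diff(L, differences = 2) >= -1e-10))
  expect_equal(pml_lorenz(a, t, 1 - 1e-9), 1, tolerance = 1e-6)
})

test_that("residual-life moments extend MRL/MIT and match quadrature", {
  expect_equal(pml_residual_moment(1, 1, 1, 1), pml_mrl(1, 1, 1),
               tolerance = 1e-10)
  expect_equal(pml_reversed_residual_moment(1, 1, 1, 2), pml_mit(1, 1, 2),
               tolerance = 1e-10)
  # E[(X-1)^2 | X > 1] at (alpha=1, theta=1)
  surv <- 1 - ppml(1, 1, 1)
  oracle <- quad(function(x) (x - 1)^2 * dpml(x, 1, 1), 1, Inf) / surv
  expect_equal(pml_residual_moment(1, 1, 2, 1), oracle, tolerance = 1e-7)
  oracle_r <- quad(function(x) (2 - x)^3 * dpml(x, 1.5, 0.8), 0, 2) /
    ppml(2, 1.5, 0.8)
  expect_equal(pml_reversed_residual_moment(1.5, 0.8, 3, 2), oracle_r,
               tolerance = 1e-7)
})
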