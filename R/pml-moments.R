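#' Moments and lifetime summaries of the PML distribution
#'
#' Closed-form raw moments, central moments, shape coefficients, the
#' moment-generating function, incomplete moments and the derived lifetime
#' summaries (mean residual life, mean inactivity time, mean deviations,
#' Bonferroni and Lorenz curves, residual-life moments).
#'
#' The r-th raw moment is
#' \deqn{\mu'_r = \frac{\Gamma(r/\alpha + 1)}{\theta^{r/\alpha}}
#'   \left[1 + \frac{r/\alpha}{2^{r/\alpha + 1}(1 + \theta)}\right],}
#' and the incomplete moments are expressed through the non-regularised
#' upper and lower incomplete gamma functions evaluated at
#' \eqn{\theta t^\alpha} and \eqn{2\theta t^\alpha}.
#'
#' @param alpha,theta PML shape and scale parameters (both positive).
#' @param r,s moment order, a nonnegative real (strictly positive for the
#'   incomplete moments).
#' @param t truncation point (age), a nonnegative real.
#' @param n integer moment order for the (reversed) residual-life moments
#'   and the central moments.
#' @param p probability in (0, 1) for the Bonferroni and Lorenz curves.
#' @param about for [pml_mean_deviation()], deviation about the `"mean"`
#'   or the `"median"`.
#'
#' @return A single numeric value.
#' @name pml-moments
NULL

# non-regularised incomplete gamma functions
.gamma_upper <- function(a, x) gamma(a) * stats::pgamma(x, a, lower.tail = FALSE)
.gamma_lower <- function(a, x) gamma(a) * stats::pgamma(x, a, lower.tail = TRUE)

#' @rdname pml-moments
#' @export
pml_moment <- function(alpha, theta, r) {
  .check_params(alpha, theta)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0)
    stop("`r` must be a single nonnegative number", call. = FALSE)
  k <- r / alpha
  gamma(k + 1) / theta^k * (1 + k / (2^(k + 1) * (1 + theta)))
}

#' @rdname pml-moments
#' @export
pml_central_moment <- function(alpha, theta, n) {
  .check_params(alpha, theta)
  if (length(n) != 1L || n < 0 || n != round(n))
    stop("`n` must be a nonnegative integer", call. = FALSE)
  mu <- pml_moment(alpha, theta, 1)
  sum(vapply(0:n, function(r)
    choose(n, r) * (-mu)^(n - r) * pml_moment(alpha, theta, r), numeric(1)))
}

#' @rdname pml-moments
#' @export
pml_skewness <- function(alpha, theta) {
  m <- vapply(1:3, function(r) pml_moment(alpha, theta, r), numeric(1))
  (m[3] - 3 * m[2] * m[1] + 2 * m[1]^3) / (m[2] - m[1]^2)^1.5
}

#' @rdname pml-moments
#' @export
pml_kurtosis <- function(alpha, theta) {
  m <- vapply(1:4, function(r) pml_moment(alpha, theta, r), numeric(1))
  (m[4] - 4 * m[3] * m[1] + 6 * m[2] * m[1]^2 - 3 * m[1]^4) / (m[2] - m[1]^2)^2
}

#' Moment-generating function of the PML distribution
#'
#' Evaluated by adaptive quadrature of \eqn{e^{tx} f(x)}.  The integral
#' converges for every \eqn{t \le 0}; for \eqn{t > 0} it converges when
#' `alpha > 1`, and when `alpha == 1` only for \eqn{t < \theta} (the
#' survival tail decays like \eqn{e^{-\theta x}}).  Arguments outside the
#' region of convergence are rejected.
#'
#' @inheritParams pml-moments
#' @param t evaluation point of the mgf.
#' @return The value of \eqn{E[e^{tX}]}.
#' @export
pml_mgf <- function(alpha, theta, t) {
  .check_params(alpha, theta)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("`t` must be a single finite number", call. = FALSE)
  if (t > 0) {
    if (alpha < 1 || (alpha == 1 && t >= theta))
      stop("mgf diverges at t = ", t, " for alpha = ", alpha,
           ", theta = ", theta, call. = FALSE)
  }
  if (t == 0) return(1)
  stats::integrate(function(x) exp(t * x + dpml(x, alpha, theta, log = TRUE)),
                   0, Inf, rel.tol = 1e-10)$value
}

#' @rdname pml-moments
#' @export
pml_upper_inc_moment <- function(alpha, theta, s, t) {
  .check_params(alpha, theta)
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("`s` must be strictly positive", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("`t` must be nonnegative", call. = FALSE)
  k <- s / alpha
  u <- theta * t^alpha
  (1 / theta^k) * (.gamma_upper(k + 1, u) +
    (.gamma_upper(k + 2, 2 * u) - .gamma_upper(k + 1, 2 * u)) /
      ((theta + 1) * 2^(k + 1)))
}

#' @rdname pml-moments
#' @export
pml_lower_inc_moment <- function(alpha, theta, s, t) {
  .check_params(alpha, theta)
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("`s` must be strictly positive", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("`t` must be nonnegative", call. = FALSE)
  k <- s / alpha
  u <- theta * t^alpha
  (1 / theta^k) * (.gamma_lower(k + 1, u) +
    (.gamma_lower(k + 2, 2 * u) - .gamma_lower(k + 1, 2 * u)) /
      ((theta + 1) * 2^(k + 1)))
}

# E[X^s 1{X > t}] allowing s = 0 (gives the survival function), used by the
# binomial expansions of the residual-life moments.
.inc_moment0 <- function(alpha, theta, s, t, upper = TRUE) {
  if (s == 0) {
    pr <- ppml(t, alpha, theta, lower.tail = !upper)
    return(pr)
  }
  if (upper) pml_upper_inc_moment(alpha, theta, s, t)
  else pml_lower_inc_moment(alpha, theta, s, t)
}

#' @rdname pml-moments
#' @export
pml_mrl <- function(alpha, theta, t) {
  .check_params(alpha, theta)
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("`t` must be nonnegative", call. = FALSE)
  surv <- ppml(t, alpha, theta, lower.tail = FALSE)
  if (surv <= 1e-300)
    stop("survival is numerically zero at t = ", t, call. = FALSE)
  pml_upper_inc_moment(alpha, theta, 1, t) / surv - t
}

#' @rdname pml-moments
#' @export
pml_mit <- function(alpha, theta, t) {
  .check_params(alpha, theta)
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stop("`t` must be strictly positive", call. = FALSE)
  Ft <- ppml(t, alpha, theta)
  if (Ft <= 1e-300)
    stop("distribution function is numerically zero at t = ", t, call. = FALSE)
  t - pml_lower_inc_moment(alpha, theta, 1, t) / Ft
}

#' @rdname pml-moments
#' @export
pml_mean_deviation <- function(alpha, theta, about = c("mean", "median")) {
  about <- match.arg(about)
  .check_params(alpha, theta)
  mu <- pml_moment(alpha, theta, 1)
  if (about == "mean") {
    2 * mu * ppml(mu, alpha, theta) - 2 * mu +
      2 * pml_upper_inc_moment(alpha, theta, 1, mu)
  } else {
    med <- qpml(0.5, alpha, theta)
    2 * pml_upper_inc_moment(alpha, theta, 1, med) - mu
  }
}

#' @rdname pml-moments
#' @export
pml_lorenz <- function(alpha, theta, p) {
  .check_params(alpha, theta)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("`p` must lie in (0, 1]", call. = FALSE)
  if (p == 1) return(1)
  q <- qpml(p, alpha, theta)
  pml_lower_inc_moment(alpha, theta, 1, q) / pml_moment(alpha, theta, 1)
}

#' @rdname pml-moments
#' @export
pml_bonferroni <- function(alpha, theta, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  pml_lorenz(alpha, theta, p) / p
}

#' @rdname pml-moments
#' @export
pml_residual_moment <- function(alpha, theta, n, t) {
  .check_params(alpha, theta)
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  surv <- ppml(t, alpha, theta, lower.tail = FALSE)
  if (surv <= 1e-300)
    stop("survival is numerically zero at t = ", t, call. = FALSE)
  acc <- sum(vapply(0:n, function(s)
    choose(n, s) * (-t)^(n - s) * .inc_moment0(alpha, theta, s, t, upper = TRUE),
    numeric(1)))
  acc / surv
}

#' @rdname pml-moments
#' @export
pml_reversed_residual_moment <- function(alpha, theta, n, t) {
  .check_params(alpha, theta)
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  Ft <- ppml(t, alpha, theta)
  if (Ft <= 1e-300)
    stop("distribution function is numerically zero at t = ", t, call. = FALSE)
  acc <- sum(vapply(0:n, function(s)
    choose(n, s) * t^(n - s) * (-1)^s *
      .inc_moment0(alpha, theta, s, t, upper = FALSE), numeric(1)))
  acc / Ft
}
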