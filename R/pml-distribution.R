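#' The power-modified Lindley distribution
#'
#' Density, distribution function, quantile function, hazard rate and random
#' generation for the power-modified Lindley (PML) distribution with shape
#' `alpha` and scale `theta`.  The PML law is the distribution of
#' \eqn{T^{1/\alpha}} where \eqn{T} follows the one-parameter modified
#' Lindley distribution, so `alpha = 1` recovers the modified Lindley
#' distribution itself.
#'
#' The cumulative distribution function is
#' \deqn{F(x) = 1 - e^{-\theta x^\alpha}\left[1 +
#'   \frac{\theta x^\alpha}{\theta + 1} e^{-\theta x^\alpha}\right],
#'   \qquad x > 0,}
#' and the density is
#' \deqn{f(x) = \frac{\theta\alpha}{\theta + 1} e^{-2\theta x^\alpha}
#'   x^{\alpha-1}\left[(1+\theta) e^{\theta x^\alpha} +
#'   2\theta x^\alpha - 1\right].}
#'
#' The density is evaluated in log space: the product
#' \eqn{e^{-2\theta x^\alpha} e^{\theta x^\alpha}} is combined before
#' exponentiating, so the functions remain finite for large
#' \eqn{\theta x^\alpha} where the bracket alone would overflow.
#'
#' @param x,q vector of quantiles.  `dpml` and `hpml` require strictly
#'   positive values; `ppml` accepts zero.
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations to generate.
#' @param alpha shape parameter, `alpha > 0`.
#' @param theta scale parameter, `theta > 0`.
#' @param log,log.p logical; if `TRUE` probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#'
#' @return `dpml` gives the density, `ppml` the distribution function,
#'   `qpml` the quantile function, `hpml` the hazard rate and `rpml`
#'   generates random deviates.
#'
#' @examples
#' dpml(1, alpha = 1, theta = 1)        # 0.5 * exp(-2) * (2 * exp(1) + 1)
#' ppml(1, alpha = 1, theta = 1)        # 1 - exp(-1) - 0.5 * exp(-2)
#' qpml(ppml(2, 2, 0.5), 2, 0.5)        # 2
#' @name pml
NULL

.check_params <- function(alpha, theta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single finite positive number", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("`theta` must be a single finite positive number", call. = FALSE)
  invisible(TRUE)
}

.check_sample <- function(x, name = "x") {
  if (length(x) == 0L) stop("`", name, "` must be nonempty", call. = FALSE)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x <= 0))
    stop("`", name, "` must contain only finite, strictly positive values",
         call. = FALSE)
  invisible(TRUE)
}

#' @rdname pml
#' @export
dpml <- function(x, alpha, theta, log = FALSE) {
  .check_params(alpha, theta)
  if (any(x <= 0 | !is.finite(x)))
    stop("`x` must be strictly positive and finite for the density", call. = FALSE)
  u <- theta * x^alpha
  # (2u - 1) e^{-u} -> 0 as u -> Inf; guard the Inf * 0 indeterminate form
  damp <- ifelse(u > 700, 0, (2 * u - 1) * exp(-u))
  # log f = log(theta a / (1+theta)) + (a-1) log x - u + log(1+theta + (2u-1) e^{-u})
  lf <- log(theta) + log(alpha) - log1p(theta) + (alpha - 1) * log(x) -
    u + log(1 + theta + damp)
  if (log) lf else exp(lf)
}

#' @rdname pml
#' @export
ppml <- function(q, alpha, theta, lower.tail = TRUE, log.p = FALSE) {
  .check_params(alpha, theta)
  if (any(q < 0 | !is.finite(q)))
    stop("`q` must be nonnegative and finite", call. = FALSE)
  u <- theta * q^alpha
  ue <- ifelse(u > 700, 0, u * exp(-u))
  surv <- exp(-u) * (1 + ue / (theta + 1))
  p <- if (lower.tail) 1 - surv else surv
  if (log.p) log(p) else p
}

# Survival on (0, Inf) via the scale-free variable u = theta * x^alpha.
.pml_surv_u <- function(u, theta) exp(-u) * (1 + u * exp(-u) / (theta + 1))

#' @rdname pml
#' @export
qpml <- function(p, alpha, theta, lower.tail = TRUE, log.p = FALSE) {
  .check_params(alpha, theta)
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  # The cdf depends on x only through u = theta x^alpha, so invert once in u
  # by bracketed root finding and map back: x = (u / theta)^(1/alpha).
  vapply(p, function(pp) {
    g <- function(u) .pml_surv_u(u, theta) - (1 - pp)
    hi <- 1
    while (g(hi) > 0) hi <- hi * 2
    lo <- hi / 2
    while (g(lo) < 0) lo <- lo / 2
    u <- stats::uniroot(g, c(lo, hi), tol = 1e-14 * max(1, hi))$root
    (u / theta)^(1 / alpha)
  }, numeric(1))
}

#' @rdname pml
#' @export
hpml <- function(x, alpha, theta, log = FALSE) {
  .check_params(alpha, theta)
  if (any(x <= 0 | !is.finite(x)))
    stop("`x` must be strictly positive and finite for the hazard", call. = FALSE)
  u <- theta * x^alpha
  ue <- ifelse(u > 700, 0, u * exp(-u))
  lsurv <- -u + log1p(ue / (theta + 1))
  lh <- dpml(x, alpha, theta, log = TRUE) - lsurv
  if (log) lh else exp(lh)
}

#' @rdname pml
#' @export
rpml <- function(n, alpha, theta) {
  .check_params(alpha, theta)
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  qpml(stats::runif(n), alpha, theta)
}
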