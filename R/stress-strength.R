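#' Stress-strength reliability of two PML laws with a common shape
#'
#' Closed-form \eqn{R = P(Y < X)} for independent strength
#' \eqn{X \sim \mathrm{PML}(\alpha, \theta_1)} and stress
#' \eqn{Y \sim \mathrm{PML}(\alpha, \theta_2)}.  The substitution
#' \eqn{t = x^\alpha} removes \eqn{\alpha}, so R depends only on the two
#' rates:
#' \deqn{R = 1 - I_1 - \frac{\theta_2}{\theta_2 + 1} I_2,}
#' \deqn{I_1 = \frac{\theta_1}{\theta_1+1}\left[\frac{1+\theta_1}
#'   {\theta_1+\theta_2} + \frac{2\theta_1}{(2\theta_1+\theta_2)^2}
#'   - \frac{1}{2\theta_1+\theta_2}\right],}
#' \deqn{I_2 = \frac{\theta_1}{\theta_1+1}\left[\frac{1+\theta_1}
#'   {(\theta_1+2\theta_2)^2} + \frac{\theta_1}{2(\theta_1+\theta_2)^3}
#'   - \frac{1}{4(\theta_1+\theta_2)^2}\right].}
#' This form satisfies \eqn{R = 1/2} exactly at \eqn{\theta_1 = \theta_2}
#' (i.i.d. continuous variables) and agrees with adaptive quadrature of
#' \eqn{\int F_Y f_X} to near machine precision.
#'
#' @param theta1 strength rate, positive.
#' @param theta2 stress rate, positive.
#' @return The reliability, a probability.
#' @seealso [ss_reliability_printed()] for a legacy closed-form variant.
#' @examples
#' ss_reliability(1, 2)      # about 0.70559
#' ss_reliability(3, 3)      # exactly 0.5
#' @export
ss_reliability <- function(theta1, theta2) {
  if (!is.numeric(theta1) || !is.numeric(theta2) ||
      any(!is.finite(theta1)) || any(!is.finite(theta2)) ||
      any(theta1 <= 0) || any(theta2 <= 0))
    stop("`theta1` and `theta2` must be finite and positive", call. = FALSE)
  t1 <- theta1; t2 <- theta2
  I1 <- t1 / (t1 + 1) * ((1 + t1) / (t1 + t2) + 2 * t1 / (2 * t1 + t2)^2 -
                           1 / (2 * t1 + t2))
  I2 <- t1 / (t1 + 1) * ((1 + t1) / (t1 + 2 * t2)^2 +
                           t1 / (2 * (t1 + t2)^3) -
                           1 / (4 * (t1 + t2)^2))
  1 - I1 - t2 / (t2 + 1) * I2
}

#' Legacy closed-form reliability (as printed in the source derivation)
#'
#' A faithful transcription of a published closed form for
#' \eqn{R = P(Y < X)} that circulates with the PML stress-strength model.
#' It does **not** satisfy the \eqn{\theta_1 = \theta_2 \Rightarrow R = 1/2}
#' identity and disagrees with numerical quadrature of
#' \eqn{\int F_Y f_X}; it is retained only to reproduce and diagnose
#' legacy reported values.  The result carries attribute
#' `validated = FALSE` and evaluating it emits a warning.
#'
#' @inheritParams ss_reliability
#' @return The (non-validated) value with attribute `validated = FALSE`.
#' @export
ss_reliability_printed <- function(theta1, theta2) {
  if (any(theta1 <= 0) || any(theta2 <= 0))
    stop("`theta1` and `theta2` must be positive", call. = FALSE)
  warning("ss_reliability_printed() is a non-validated legacy formula; ",
          "use ss_reliability() for analysis", call. = FALSE)
  t1 <- theta1; t2 <- theta2
  A <- (t1 + 1) / (t1 + t2) + 2 * t1 / (2 * t1 + t2)^2 - 1 / (2 * t1 + t2)
  B <- (t1 + 1) / (t1 + 2 * t2) + t1 / (2 * t1 + t2)^2 - 1 / (2 * t1 + t2)
  r <- 1 - t1 / (t1 + 1) * A - t1 * t2 / ((t1 + 1) * (t2 + 1)) * B
  attr(r, "validated") <- FALSE
  r
}

# analytic gradient of ss_reliability in (theta1, theta2); the expression
# is algebraic so stats::deriv() differentiates it exactly.
.ss_reliability_grad <- local({
  expr <- expression(
    1 - t1 / (t1 + 1) * ((1 + t1) / (t1 + t2) + 2 * t1 / (2 * t1 + t2)^2 -
                           1 / (2 * t1 + t2)) -
      t2 / (t2 + 1) * (t1 / (t1 + 1) * ((1 + t1) / (t1 + 2 * t2)^2 +
                                          t1 / (2 * (t1 + t2)^3) -
                                          1 / (4 * (t1 + t2)^2))))
  dfun <- stats::deriv(expr[[1]], c("t1", "t2"), function.arg = c("t1", "t2"))
  function(theta1, theta2) {
    g <- attr(dfun(theta1, theta2), "gradient")
    c(theta1 = g[1, "t1"], theta2 = g[1, "t2"])
  }
})

#' Joint log-likelihood of the stress-strength model
#'
#' Sum of the PML log-likelihoods of the strength sample `x` at
#' \eqn{(\alpha, \theta_1)} and the stress sample `y` at
#' \eqn{(\alpha, \theta_2)} (the shape is common to both).
#'
#' @param x strength sample.
#' @param y stress sample.
#' @param alpha common shape.
#' @param theta1,theta2 strength and stress rates.
#' @return A single number.
#' @export
ss_loglik <- function(x, y, alpha, theta1, theta2) {
  pml_loglik(x, alpha, theta1) + pml_loglik(y, alpha, theta2)
}

#' @rdname ss_loglik
#' @export
ss_score <- function(x, y, alpha, theta1, theta2) {
  sx <- pml_score(x, alpha, theta1)
  sy <- pml_score(y, alpha, theta2)
  c(alpha = unname(sx["alpha"] + sy["alpha"]),
    theta1 = unname(sx["theta"]), theta2 = unname(sy["theta"]))
}

#' Joint maximum-likelihood fit of the stress-strength model
#'
#' Maximises the joint log-likelihood over
#' \eqn{(\log\alpha, \log\theta_1, \log\theta_2)} (BFGS with analytic
#' gradient, multi-start, Nelder-Mead polish).  The reliability estimate
#' is [ss_reliability()] at the fitted rates; its standard error is the
#' delta method \eqn{\sigma_R^2 = B^\top I^{-1} B} with \eqn{I} the
#' observed information and
#' \eqn{B = (0, \partial R/\partial\theta_1, \partial R/\partial\theta_2)}
#' (the first component is identically zero because R is free of
#' \eqn{\alpha}; the rate derivatives are analytic).  The confidence
#' interval for R is clipped to [0, 1]; the unclipped interval is also
#' returned.
#'
#' @param x strength sample (n >= 3).
#' @param y stress sample (m >= 3).
#' @param level confidence level.
#' @return An object of class `pml_ss_fit`: list with `estimate`
#'   (alpha, theta1, theta2), `se`, `vcov`, `ci`, `loglik`, `converged`,
#'   `r` (reliability), `r_se`, `r_ci` (clipped), `r_ci_unclipped`, `n`,
#'   `m`.
#' @examples
#' fit <- fit_ss_mle(pml_data("jute_gauge10"), pml_data("jute_gauge20"))
#' fit$r
#' @export
fit_ss_mle <- function(x, y, level = 0.95) {
  .check_sample(x, "x"); .check_sample(y, "y")
  if (length(x) < 3L || length(y) < 3L)
    stop("need at least 3 observations in each sample", call. = FALSE)
  negll <- function(lp) {
    p <- exp(lp)
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1e8)) return(1e10)
    v <- -ss_loglik(x, y, p[1], p[2], p[3])
    if (!is.finite(v)) 1e10 else v
  }
  grad <- function(lp) {
    p <- exp(lp)
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1e8)) return(numeric(3))
    g <- -ss_score(x, y, p[1], p[2], p[3]) * p
    if (any(!is.finite(g))) numeric(3) else g
  }
  fx <- fit_pml(x); fy <- fit_pml(y)
  starts <- list()
  if (fx$converged && fy$converged) {
    a0 <- mean(c(fx$estimate["alpha"], fy$estimate["alpha"]))
    starts <- list(c(a0, fx$estimate["theta"], fy$estimate["theta"]))
  }
  starts <- c(starts, lapply(c(0.5, 1, 2), function(a)
    c(a, (gamma(1 / a + 1) / mean(x))^a, (gamma(1 / a + 1) / mean(y))^a)))
  best <- .fit_positive(negll, grad, starts)
  if (is.null(best) || best$value >= 1e10)
    stop("stress-strength MLE failed to converge", call. = FALSE)
  est <- exp(best$par)
  names(est) <- c("alpha", "theta1", "theta2")
  H <- .num_hessian(function(p) ss_loglik(x, y, p[1], p[2], p[3]), est)
  vc <- solve(-H)
  dimnames(vc) <- list(names(est), names(est))
  se <- sqrt(pmax(diag(vc), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = est - z * se, upper = est + z * se)
  r <- ss_reliability(est["theta1"], est["theta2"])
  gr <- .ss_reliability_grad(est["theta1"], est["theta2"])
  B <- c(0, gr)
  r_var <- drop(t(B) %*% vc %*% B)
  r_se <- sqrt(max(r_var, 0))
  r_ci_raw <- c(lower = r - z * r_se, upper = r + z * r_se)
  sc <- ss_score(x, y, est[1], est[2], est[3])
  structure(list(estimate = est, se = se, vcov = vc, ci = ci,
                 loglik = -best$value,
                 converged = isTRUE(best$convergence == 0 &&
                   sqrt(sum(sc^2)) < 1e-4 * max(1, abs(best$value))),
                 n_iter = best$n_iter,
                 r = unname(r), r_se = r_se,
                 r_ci = pmin(pmax(r_ci_raw, 0), 1),
                 r_ci_unclipped = r_ci_raw,
                 level = level, n = length(x), m = length(y)),
            class = "pml_ss_fit")
}

#' @export
print.pml_ss_fit <- function(x, digits = 4, ...) {
  cat("Stress-strength PML fit (n =", x$n, ", m =", x$m, ")\n")
  print(round(cbind(estimate = x$estimate, se = x$se, x$ci), digits))
  cat(sprintf("R = P(Y < X) = %.*f  (se %.*f, %d%% CI %.*f-%.*f)\n",
              digits, x$r, digits, x$r_se, round(100 * x$level),
              digits, x$r_ci[1], digits, x$r_ci[2]))
  invisible(x)
}

#' @export
#' @method tidy pml_ss_fit
tidy.pml_ss_fit <- function(x, ...) {
  tibble::tibble(term = c(names(x$estimate), "R"),
                 estimate = c(unname(x$estimate), x$r),
                 std.error = c(unname(x$se), x$r_se),
                 conf.low = c(unname(x$ci[, 1]), x$r_ci[[1]]),
                 conf.high = c(unname(x$ci[, 2]), x$r_ci[[2]]))
}

#' Bayesian stress-strength analysis
#'
#' Three-parameter Metropolis-Hastings random walk on
#' \eqn{(\log\alpha, \log\theta_1, \log\theta_2)} with independent gamma
#' priors, initialised at the joint MLE.  The reliability is evaluated
#' draw-by-draw through [ss_reliability()]; point estimates under every
#' loss and the HPD interval of the R draws are reported.
#'
#' @param x,y strength and stress samples.
#' @param priors list of three `c(shape, rate)` gamma priors (alpha,
#'   theta1, theta2); if `NULL`, bootstrap-elicited from each sample.
#' @param k bootstrap resamples for elicitation.
#' @param n_iter,burn_in chain length.
#' @param c_linex,b_entropy reported LINEX / entropy shapes.
#' @param level HPD credible level.
#' @param seed integer seed.
#' @return An object of class `pml_ss_bayes`: list with `estimates`
#'   (tibble over alpha, theta1, theta2, R), `hpd`, `chain` (draws
#'   include an `R` column), `priors`.
#' @export
fit_ss_bayes <- function(x, y, priors = NULL, k = 100, n_iter = 10000,
                         burn_in = 2000, c_linex = c(-1.5, 1.5),
                         b_entropy = c(-1.5, 1.5), level = 0.95,
                         seed = 20220222) {
  .check_sample(x, "x"); .check_sample(y, "y")
  mle <- fit_ss_mle(x, y)
  if (is.null(priors)) {
    px <- .bootstrap_priors(x, k = k, seed = seed)
    py <- .bootstrap_priors(y, k = k, seed = seed + 1L)
    # alpha prior pooled across the two marginal elicitations
    priors <- list(alpha = (px[[1]] + py[[1]]) / 2,
                   theta1 = px[[2]], theta2 = py[[2]])
  }
  logtarget <- function(p) {
    ll <- tryCatch(ss_loglik(x, y, p[1], p[2], p[3]),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(vapply(1:3, function(j)
      (priors[[j]][1] - 1) * log(p[j]) - priors[[j]][2] * p[j], numeric(1)))
  }
  ch <- .mh_chain(logtarget, init = mle$estimate,
                  scales = c(0.05, 0.1, 0.1), n_iter = n_iter,
                  burn_in = burn_in, seed = seed + 2L)
  colnames(ch$draws) <- c("alpha", "theta1", "theta2")
  r_draws <- ss_reliability(ch$draws[, "theta1"], ch$draws[, "theta2"])
  draws <- cbind(ch$draws, R = r_draws)
  ch$draws <- draws
  ch$param_names <- colnames(draws)
  class(ch) <- "pml_chain"
  est <- .loss_table(draws, c_linex, b_entropy)
  hpd <- lapply(colnames(draws), function(p)
    hpd_interval(draws[, p], level = level))
  names(hpd) <- colnames(draws)
  structure(list(estimates = est, hpd = hpd, chain = ch, priors = priors,
                 mle = mle, level = level, seed = seed),
            class = "pml_ss_bayes")
}

#' @export
print.pml_ss_bayes <- function(x, digits = 4, ...) {
  cat("Bayesian stress-strength PML fit (", nrow(x$chain$draws),
      "retained draws )\n")
  print(x$estimates, n = Inf)
  for (p in names(x$hpd))
    cat(sprintf("%s %d%% HPD: (%.*f, %.*f)\n", p, round(100 * x$level),
                digits, x$hpd[[p]]$lower, digits, x$hpd[[p]]$upper))
  invisible(x)
}
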