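#' Elicit gamma-prior hyperparameters from replicate estimates
#'
#' Moment-matches independent gamma priors to a collection of replicate
#' parameter estimates: for each parameter the prior shape is
#' \eqn{w = \bar{m}^2 / v} and the prior rate \eqn{q = \bar{m} / v},
#' where \eqn{\bar{m}} and \eqn{v} are the sample mean and (k-1
#' denominator) sample variance of the k replicate estimates.  The
#' returned priors reproduce the replicate mean (`w/q`) and variance
#' (`w/q^2`) exactly.
#'
#' In data analyses the replicates are typically maximum-likelihood
#' refits of nonparametric bootstrap resamples of the observed sample
#' (see [bayes_fit_pml()]).
#'
#' @param replicates numeric matrix (k x p) or vector of replicate
#'   estimates, one column per parameter, k >= 2.
#' @return A list with one `c(shape = w, rate = q)` vector per column.
#' @examples
#' elicit_gamma_priors(cbind(alpha = c(1, 2, 3)))  # w = 4, q = 2
#' @export
elicit_gamma_priors <- function(replicates) {
  if (is.null(dim(replicates))) replicates <- cbind(replicates)
  if (nrow(replicates) < 2L)
    stop("need at least 2 replicate estimates", call. = FALSE)
  out <- lapply(seq_len(ncol(replicates)), function(j) {
    v <- replicates[, j]
    m <- mean(v); s2 <- stats::var(v)
    if (!is.finite(s2) || s2 <= 0)
      stop("replicate estimates have zero variance; supply a prior manually",
           call. = FALSE)
    c(shape = m^2 / s2, rate = m / s2)
  })
  names(out) <- colnames(replicates)
  out
}

#' Log posterior kernel of the PML parameters
#'
#' Likelihood times independent gamma priors, up to the (intractable)
#' normalisation constant:
#' \deqn{\log \pi(\alpha, \theta \mid x) = \ell(\alpha, \theta) +
#'   (w_1 - 1)\log\alpha - q_1\alpha + (w_2 - 1)\log\theta - q_2\theta
#'   + \mathrm{const}.}
#' Differences of the returned value between two parameter points are
#' exact.  Invalid parameters return `-Inf` (a sentinel for use inside
#' the sampler).
#'
#' @param x sample of strictly positive values.
#' @param alpha,theta parameter point.
#' @param priors list of two `c(shape, rate)` vectors, for `alpha` and
#'   `theta` in that order (as returned by [elicit_gamma_priors()]).
#' @return A single number (possibly `-Inf`).
#' @export
pml_log_posterior <- function(x, alpha, theta, priors) {
  if (!is.finite(alpha) || !is.finite(theta) || alpha <= 0 || theta <= 0)
    return(-Inf)
  ll <- tryCatch(pml_loglik(x, alpha, theta), error = function(e) -Inf)
  if (!is.finite(ll)) return(-Inf)
  ll + (priors[[1]][[1]] - 1) * log(alpha) - priors[[1]][[2]] * alpha +
    (priors[[2]][[1]] - 1) * log(theta) - priors[[2]][[2]] * theta
}

# Generic Gaussian random-walk Metropolis-Hastings on the log-parameter
# scale with the induced Jacobian in the acceptance ratio.  `logtarget`
# takes the natural-scale parameter vector.  Proposal scales adapt towards
# an acceptance rate near 0.3 during burn-in only, so detailed balance
# holds for the retained draws.
.mh_chain <- function(logtarget, init, scales, n_iter, burn_in, seed,
                      adapt = TRUE) {
  stopifnot(n_iter > burn_in, burn_in >= 0, all(init > 0), all(scales > 0))
  set.seed(seed)
  k <- length(init)
  cur <- log(init)
  lp_cur <- logtarget(exp(cur)) + sum(cur)  # + log Jacobian
  if (!is.finite(lp_cur)) stop("log target not finite at the initial point")
  draws <- matrix(NA_real_, n_iter, k)
  acc <- logical(n_iter)
  block_acc <- 0L
  for (i in seq_len(n_iter)) {
    prop <- cur + stats::rnorm(k, 0, scales)
    lp_prop <- logtarget(exp(prop)) + sum(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
      cur <- prop; lp_cur <- lp_prop; acc[i] <- TRUE
      block_acc <- block_acc + 1L
    }
    draws[i, ] <- exp(cur)
    if (adapt && i <= burn_in && i %% 100L == 0L) {
      rate <- block_acc / 100
      scales <- scales * exp(rate - 0.3)
      block_acc <- 0L
    }
  }
  keep <- (burn_in + 1L):n_iter
  list(draws = draws[keep, , drop = FALSE],
       acceptance_rate = mean(acc[keep]),
       burn_in = burn_in, n_iter = n_iter, seed = seed, scales = scales)
}

#' Metropolis-Hastings sampler for the PML posterior
#'
#' Gaussian random walk on \eqn{(\log\alpha, \log\theta)} targeting the
#' posterior kernel of [pml_log_posterior()], with the change-of-variable
#' Jacobian included in the acceptance ratio so the retained draws target
#' the posterior of the natural-scale parameters.  The chain starts at
#' the maximum-likelihood estimate; proposal scales are adapted during
#' burn-in only and frozen afterwards.
#'
#' @param x sample of strictly positive values.
#' @param priors list of two `c(shape, rate)` gamma priors (alpha, theta).
#' @param n_iter total iterations (default 10000).
#' @param burn_in discarded initial iterations (default 2000).
#' @param proposal_scale initial standard deviations of the log-scale
#'   random walk (length 2).
#' @param seed integer seed; the chain is bit-reproducible given the seed
#'   and configuration.
#' @return An object of class `pml_chain`: list with `draws` (matrix,
#'   post burn-in, columns `alpha`, `theta`), `acceptance_rate`,
#'   `burn_in`, `n_iter`, `seed`.
#' @export
mh_sample_pml <- function(x, priors, n_iter = 10000, burn_in = 2000,
                          proposal_scale = c(0.1, 0.1), seed = 20220222) {
  .check_sample(x)
  mle <- fit_pml(x)
  if (!mle$converged)
    stop("MLE did not converge; cannot initialise the sampler", call. = FALSE)
  ch <- .mh_chain(function(p) pml_log_posterior(x, p[1], p[2], priors),
                  init = mle$estimate, scales = proposal_scale,
                  n_iter = n_iter, burn_in = burn_in, seed = seed)
  colnames(ch$draws) <- c("alpha", "theta")
  ch$param_names <- c("alpha", "theta")
  class(ch) <- "pml_chain"
  ch
}

#' @export
print.pml_chain <- function(x, ...) {
  cat("Metropolis-Hastings chain:", nrow(x$draws), "retained draws of",
      paste(x$param_names, collapse = ", "), "\n")
  cat("acceptance rate", round(x$acceptance_rate, 3), " burn-in",
      x$burn_in, " seed", x$seed, "\n")
  invisible(x)
}

#' Loss-based Bayes point estimates from posterior draws
#'
#' Point estimators under squared-error (`"self"`, the posterior mean),
#' LINEX (`"linex"`, \eqn{-c^{-1}\log E[e^{-c\Omega}]}) and entropy
#' (`"entropy"`, \eqn{(E[\Omega^{-b}])^{-1/b}}) loss, with expectations
#' approximated by averages over the draws.  Entropy loss with `b = -1`
#' coincides with the posterior mean.
#'
#' @param draws vector of posterior draws of one parameter.
#' @param loss one of `"self"`, `"linex"`, `"entropy"`.
#' @param c LINEX shape, nonzero (required for `"linex"`).
#' @param b entropy shape, nonzero (required for `"entropy"`).
#' @return A single number.
#' @examples
#' loss_estimate(c(1, 2, 3), "linex", c = 1)     # 1.6912...
#' loss_estimate(c(1, 2, 3), "entropy", b = 1)   # 18/11
#' @export
loss_estimate <- function(draws, loss = c("self", "linex", "entropy"),
                          c = NULL, b = NULL) {
  loss <- match.arg(loss)
  if (length(draws) == 0L) stop("`draws` must be nonempty", call. = FALSE)
  switch(loss,
    self = mean(draws),
    linex = {
      if (is.null(c) || c == 0) stop("LINEX requires nonzero `c`", call. = FALSE)
      # log-mean-exp for numerical stability
      m <- max(-c * draws)
      -(m + log(mean(exp(-c * draws - m)))) / c
    },
    entropy = {
      if (is.null(b) || b == 0) stop("entropy requires nonzero `b`", call. = FALSE)
      if (any(draws <= 0))
        stop("entropy loss requires strictly positive draws", call. = FALSE)
      mean(draws^(-b))^(-1 / b)
    })
}

#' Highest posterior density interval from sorted draws
#'
#' Chen-Shao construction: among all intervals
#' \eqn{(\omega_{(j)}, \omega_{(j + m)})} over the sorted draws with
#' \eqn{m = \lceil (1-\gamma) A \rceil}, return the shortest; ties are
#' broken by the smallest j.
#'
#' @param draws vector of posterior draws.
#' @param level credible level 1 - gamma.
#' @return List with `lower`, `upper`, `level`.
#' @examples
#' hpd_interval(1:100, level = 0.90)  # c(1, 91)
#' @export
hpd_interval <- function(draws, level = 0.95) {
  A <- length(draws)
  gamma <- 1 - level
  if (A < 1 / gamma) stop("too few draws for level ", level, call. = FALSE)
  sorted <- sort(draws)
  m <- ceiling(level * A)
  j <- seq_len(A - m)
  widths <- sorted[j + m] - sorted[j]
  jbest <- j[which.min(widths)]  # which.min takes the first minimum
  list(lower = sorted[jbest], upper = sorted[jbest + m], level = level)
}

#' Full Bayesian analysis of a PML sample
#'
#' Elicits gamma priors from k nonparametric bootstrap resamples of the
#' data (each refit by maximum likelihood and moment-matched with
#' [elicit_gamma_priors()]), runs the Metropolis-Hastings sampler, and
#' reports every loss-based point estimate together with posterior
#' standard deviations and HPD intervals per parameter.
#'
#' @param x sample of strictly positive values.
#' @param priors optional list of two `c(shape, rate)` gamma priors; if
#'   `NULL` they are bootstrap-elicited.
#' @param k number of bootstrap resamples for elicitation.
#' @param n_iter,burn_in MCMC length (see [mh_sample_pml()]).
#' @param c_linex,b_entropy LINEX and entropy shapes reported (defaults
#'   \eqn{\pm 1.5}).
#' @param level credible level of the HPD intervals.
#' @param seed integer seed controlling the bootstrap and the chain.
#' @return An object of class `pml_bayes`: list with `estimates` (a
#'   tibble: parameter, estimator, value, posterior sd), `hpd` (per
#'   parameter), `chain`, `priors`.
#' @export
bayes_fit_pml <- function(x, priors = NULL, k = 100, n_iter = 10000,
                          burn_in = 2000, c_linex = c(-1.5, 1.5),
                          b_entropy = c(-1.5, 1.5), level = 0.95,
                          seed = 20220222) {
  .check_sample(x)
  if (is.null(priors)) {
    priors <- .bootstrap_priors(x, k = k, seed = seed)
  }
  chain <- mh_sample_pml(x, priors, n_iter = n_iter, burn_in = burn_in,
                         seed = seed + 1L)
  est <- .loss_table(chain$draws, c_linex, b_entropy)
  hpd <- lapply(seq_along(chain$param_names), function(j)
    hpd_interval(chain$draws[, j], level = level))
  names(hpd) <- chain$param_names
  structure(list(estimates = est, hpd = hpd, chain = chain, priors = priors,
                 level = level, seed = seed),
            class = "pml_bayes")
}

.bootstrap_priors <- function(x, k, seed) {
  set.seed(seed)
  reps <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("alpha", "theta")))
  for (j in seq_len(k)) {
    xb <- sample(x, replace = TRUE)
    fit <- tryCatch(fit_pml(xb), error = function(e) NULL)
    if (!is.null(fit) && fit$converged) reps[j, ] <- fit$estimate
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  if (nrow(reps) < 2L)
    stop("bootstrap elicitation failed: too few converged refits", call. = FALSE)
  elicit_gamma_priors(reps)
}

.loss_table <- function(draws, c_linex, b_entropy) {
  params <- colnames(draws)
  rows <- list()
  for (p in params) {
    d <- draws[, p]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      parameter = p, estimator = "self", value = loss_estimate(d, "self"),
      sd = stats::sd(d))
    for (cc in c_linex)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = p, estimator = sprintf("linex(c=%g)", cc),
        value = loss_estimate(d, "linex", c = cc), sd = stats::sd(d))
    for (bb in b_entropy)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = p, estimator = sprintf("entropy(b=%g)", bb),
        value = loss_estimate(d, "entropy", b = bb), sd = stats::sd(d))
  }
  do.call(rbind, rows)
}

#' @export
print.pml_bayes <- function(x, digits = 4, ...) {
  cat("Bayesian PML fit (", nrow(x$chain$draws), "retained draws,",
      "acceptance", round(x$chain$acceptance_rate, 3), ")\n")
  print(x$estimates, n = Inf)
  for (p in names(x$hpd))
    cat(sprintf("%s %d%% HPD: (%.*f, %.*f)\n", p, round(100 * x$level),
                digits, x$hpd[[p]]$lower, digits, x$hpd[[p]]$upper))
  invisible(x)
}
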