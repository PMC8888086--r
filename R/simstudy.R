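#' Monte-Carlo benchmarking of the PML estimators
#'
#' Repeatedly draws PML samples by inverse-cdf transformation of
#' uniforms, applies the requested estimators, and tabulates the bias,
#' mean-squared error and mean confidence/credible-interval length of
#' each estimator for each parameter, over a grid of sample sizes.
#'
#' For the maximum-likelihood estimator the interval is the asymptotic
#' Wald interval; for the Bayesian estimators it is the HPD interval of
#' the chain.  Bayesian replicates elicit their gamma priors from
#' bootstrap refits of the replicate sample (moment matching, see
#' [elicit_gamma_priors()]) and run a shortened chain; both lengths are
#' configurable.  Replicates whose fit fails are dropped and counted.
#'
#' @param alpha,theta true parameter values.
#' @param sizes vector of sample sizes.
#' @param reps number of Monte-Carlo replicates L per cell.
#' @param estimators subset of `"mle"`, `"self"`, `"linex"`, `"entropy"`.
#'   LINEX and entropy are evaluated at both shapes in `c_linex` /
#'   `b_entropy`.
#' @param c_linex,b_entropy loss shapes (defaults \eqn{\pm 1.5}).
#' @param level nominal confidence/credible level.
#' @param n_iter,burn_in per-replicate chain length for the Bayesian
#'   estimators.
#' @param boot_k bootstrap resamples for per-replicate prior elicitation.
#' @param seed integer seed; the whole study is reproducible given the
#'   seed.
#' @return A [tibble::tibble()] of class `pml_simstudy` with one row per
#'   (n, estimator, parameter): columns `n`, `estimator`, `parameter`,
#'   `truth`, `bias`, `mse`, `ci_length`, `coverage`, `failures`, `reps`.
#'   Cells with more than 10% replicate failures are flagged in the
#'   `flagged` column.
#' @examples
#' sim_study_pml(alpha = 2, theta = 2, sizes = 35, reps = 10, seed = 1)
#' @export
sim_study_pml <- function(alpha, theta, sizes = c(35, 70, 140), reps = 500,
                          estimators = "mle", c_linex = c(-1.5, 1.5),
                          b_entropy = c(-1.5, 1.5), level = 0.95,
                          n_iter = 3000, burn_in = 1000, boot_k = 50,
                          seed = 20220222) {
  .check_params(alpha, theta)
  stopifnot(reps >= 1, length(sizes) >= 1)
  truth <- c(alpha = alpha, theta = theta)
  rows <- list()
  for (n in sizes) {
    acc <- .sim_accumulator(estimators, c_linex, b_entropy,
                            params = names(truth))
    failures <- 0L
    for (l in seq_len(reps)) {
      set.seed(seed + 7919L * match(n, sizes) + l)
      xx <- qpml(stats::runif(n), alpha, theta)
      res <- .sim_one_sample(xx, truth, estimators, c_linex, b_entropy,
                             level, n_iter, burn_in, boot_k,
                             seed = seed + 104729L + l)
      if (is.null(res)) { failures <- failures + 1L; next }
      acc <- .sim_accumulate(acc, res, truth)
    }
    rows[[length(rows) + 1L]] <-
      .sim_summarise(acc, truth, n_label = n, failures = failures,
                     reps = reps)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pml_simstudy", class(out))
  out
}

# every estimator produces, per parameter: estimate, ci lower, ci upper
.sim_one_sample <- function(xx, truth, estimators, c_linex, b_entropy,
                            level, n_iter, burn_in, boot_k, seed) {
  out <- list()
  fit <- tryCatch(fit_pml(xx, init = unname(truth), level = level),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged || any(!is.finite(fit$se))) return(NULL)
  if ("mle" %in% estimators)
    out[["mle"]] <- list(est = fit$estimate, lower = fit$ci[, 1],
                         upper = fit$ci[, 2])
  bayes_est <- setdiff(estimators, "mle")
  if (length(bayes_est) > 0) {
    bf <- tryCatch({
      priors <- .bootstrap_priors(xx, k = boot_k, seed = seed)
      chain <- mh_sample_pml(xx, priors, n_iter = n_iter,
                             burn_in = burn_in, seed = seed + 1L)
      chain
    }, error = function(e) NULL)
    if (is.null(bf)) return(NULL)
    hp <- apply(bf$draws, 2, hpd_interval, level = level)
    lo <- vapply(hp, `[[`, numeric(1), "lower")
    hi <- vapply(hp, `[[`, numeric(1), "upper")
    for (estname in .bayes_estimator_names(bayes_est, c_linex, b_entropy)) {
      est <- apply(bf$draws, 2, .apply_loss, spec = estname)
      out[[estname]] <- list(est = est, lower = lo, upper = hi)
    }
  }
  out
}

.bayes_estimator_names <- function(bayes_est, c_linex, b_entropy) {
  nm <- character(0)
  if ("self" %in% bayes_est) nm <- c(nm, "self")
  if ("linex" %in% bayes_est)
    nm <- c(nm, sprintf("linex(c=%g)", c_linex))
  if ("entropy" %in% bayes_est)
    nm <- c(nm, sprintf("entropy(b=%g)", b_entropy))
  nm
}

.apply_loss <- function(d, spec) {
  if (spec == "self") return(loss_estimate(d, "self"))
  if (grepl("^linex", spec))
    return(loss_estimate(d, "linex",
                         c = as.numeric(sub("linex\\(c=(.*)\\)", "\\1", spec))))
  loss_estimate(d, "entropy",
                b = as.numeric(sub("entropy\\(b=(.*)\\)", "\\1", spec)))
}

.sim_accumulator <- function(estimators, c_linex, b_entropy, params) {
  nm <- c(if ("mle" %in% estimators) "mle",
          .bayes_estimator_names(setdiff(estimators, "mle"),
                                 c_linex, b_entropy))
  acc <- list()
  for (e in nm)
    acc[[e]] <- list(sum = 0 * seq_along(params), sumsq = 0 * seq_along(params),
                     len = 0 * seq_along(params), cov = 0 * seq_along(params),
                     count = 0L, params = params)
  acc
}

.sim_accumulate <- function(acc, res, truth) {
  for (e in names(res)) {
    r <- res[[e]]
    acc[[e]]$sum <- acc[[e]]$sum + r$est
    acc[[e]]$sumsq <- acc[[e]]$sumsq + r$est^2
    acc[[e]]$len <- acc[[e]]$len + (r$upper - r$lower)
    acc[[e]]$covhits <- (acc[[e]]$covhits %||% 0) +
      as.numeric(r$lower <= truth & truth <= r$upper)
    acc[[e]]$count <- acc[[e]]$count + 1L
  }
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sim_summarise <- function(acc, truth, n_label, failures, reps) {
  rows <- lapply(names(acc), function(e) {
    a <- acc[[e]]
    k <- max(a$count, 1L)
    mean_est <- a$sum / k
    bias <- mean_est - truth
    mse <- a$sumsq / k - 2 * truth * mean_est + truth^2
    tibble::tibble(n = n_label, estimator = e, parameter = a$params,
                   truth = unname(truth), bias = unname(bias),
                   mse = unname(mse), ci_length = unname(a$len / k),
                   coverage = unname((a$covhits %||% rep(NA_real_,
                                                         length(truth))) / k),
                   failures = failures, reps = reps,
                   flagged = failures > 0.1 * reps)
  })
  do.call(rbind, rows)
}

#' Monte-Carlo study of the stress-strength estimators
#'
#' As [sim_study_pml()] but for the three-parameter stress-strength model
#' over a grid of (n, m) pairs; the reliability R is tracked as a fourth
#' quantity with its truth taken from the validated closed form
#' [ss_reliability()].
#'
#' @param alpha,theta1,theta2 true parameter values.
#' @param sizes list of `c(n, m)` pairs.
#' @param reps replicates per cell.
#' @param level nominal level.
#' @param seed integer seed.
#' @return A tibble with one row per (n, m, parameter) for the MLE:
#'   columns as in [sim_study_pml()] plus `m`.
#' @export
sim_study_ss <- function(alpha, theta1, theta2,
                         sizes = list(c(30, 30), c(45, 50), c(70, 60)),
                         reps = 500, level = 0.95, seed = 20220222) {
  truth <- c(alpha = alpha, theta1 = theta1, theta2 = theta2,
             R = ss_reliability(theta1, theta2))
  rows <- list()
  for (sz in sizes) {
    n <- sz[1]; m <- sz[2]
    est_sum <- est_sumsq <- len_sum <- cov_sum <- numeric(4)
    count <- 0L; failures <- 0L
    for (l in seq_len(reps)) {
      set.seed(seed + 7919L * (n + 1000L * m) + l)
      xx <- qpml(stats::runif(n), alpha, theta1)
      yy <- qpml(stats::runif(m), alpha, theta2)
      fit <- tryCatch(fit_ss_mle(xx, yy, level = level),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged || any(!is.finite(fit$se))) {
        failures <- failures + 1L; next
      }
      est <- c(fit$estimate, fit$r)
      lo <- c(fit$ci[, 1], fit$r_ci_unclipped[1])
      hi <- c(fit$ci[, 2], fit$r_ci_unclipped[2])
      est_sum <- est_sum + est
      est_sumsq <- est_sumsq + est^2
      len_sum <- len_sum + (hi - lo)
      cov_sum <- cov_sum + as.numeric(lo <= truth & truth <= hi)
      count <- count + 1L
    }
    k <- max(count, 1L)
    mean_est <- est_sum / k
    rows[[length(rows) + 1L]] <- tibble::tibble(
      n = n, m = m, estimator = "mle", parameter = names(truth),
      truth = unname(truth), bias = unname(mean_est - truth),
      mse = unname(est_sumsq / k - 2 * truth * mean_est + truth^2),
      ci_length = unname(len_sum / k), coverage = unname(cov_sum / k),
      failures = failures, reps = reps, flagged = failures > 0.1 * reps)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pml_simstudy", class(out))
  out
}
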