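#' Comparator lifetime families
#'
#' Maximum-likelihood fits of four standard lifetime families used as
#' benchmarks for the PML model.  Parametrizations:
#' power Lindley \eqn{F(x) = 1 - (1 + \theta x^\beta/(\theta+1))
#' e^{-\theta x^\beta}}; Weibull \eqn{F(x) = 1 - e^{-(x/\lambda)^\beta}};
#' inverse Weibull \eqn{F(x) = e^{-(\lambda/x)^\beta}}; Lomax
#' \eqn{F(x) = 1 - (1 + x/\lambda)^{-\beta}}.
#'
#' @param x sample of strictly positive values.
#' @param family one of `"power_lindley"`, `"weibull"`,
#'   `"inverse_weibull"`, `"lomax"`.
#' @param level confidence level for the Wald intervals.
#' @return A `pml_fit` object (see [fit_pml()]).
#' @export
fit_comparator <- function(x,
                           family = c("power_lindley", "weibull",
                                      "inverse_weibull", "lomax"),
                           level = 0.95) {
  family <- match.arg(family)
  .check_sample(x)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  fam <- .families[[family]]
  negll <- function(lp) {
    p <- exp(lp)
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1e12)) return(1e10)
    v <- suppressWarnings(-sum(fam$lpdf(x, p[1], p[2])))
    if (!is.finite(v)) 1e10 else v
  }
  best <- .fit_positive(negll, grad = NULL, starts = fam$starts(x))
  if (is.null(best) || best$value >= 1e10) return(.fit_failure(x, family))
  est <- exp(best$par)
  names(est) <- fam$par_names
  .make_fit(est, -best$value, function(p) sum(fam$lpdf(x, p[1], p[2])),
            x, level, best$convergence == 0, best$n_iter, family = family)
}

#' Distribution function of a fitted model
#'
#' Returns the cdf of a `pml_fit` as a function of one argument, for use
#' with [gof_test()].
#'
#' @param fit a `pml_fit` object.
#' @return A function `function(x)` evaluating the fitted cdf.
#' @export
fitted_cdf <- function(fit) {
  stopifnot(inherits(fit, "pml_fit"))
  p <- fit$estimate
  if (fit$family == "pml") return(function(x) ppml(x, p[1], p[2]))
  cdf <- .families[[fit$family]]$cdf
  function(x) cdf(x, p[1], p[2])
}

.families <- list(
  pml = list(
    par_names = c("alpha", "theta"),
    lpdf = function(x, a, t) dpml(x, a, t, log = TRUE),
    cdf = function(x, a, t) ppml(x, a, t),
    starts = function(x) .pml_starts(x)),
  power_lindley = list(
    par_names = c("beta", "theta"),
    lpdf = function(x, b, t)
      2 * log(t) + log(b) - log1p(t) + (b - 1) * log(x) +
        log1p(x^b) - t * x^b,
    cdf = function(x, b, t) 1 - (1 + t * x^b / (t + 1)) * exp(-t * x^b),
    starts = function(x) {
      m <- mean(x)
      lapply(c(0.5, 1, 2, 4), function(b) c(b, (1 / m)^b + 1 / m))
    }),
  weibull = list(
    par_names = c("beta", "lambda"),
    lpdf = function(x, b, l) stats::dweibull(x, shape = b, scale = l,
                                             log = TRUE),
    cdf = function(x, b, l) stats::pweibull(x, shape = b, scale = l),
    starts = function(x) {
      # Weibull plotting-position regression start plus coarse grid
      lx <- log(x)
      b0 <- max(0.1, 1.2 / stats::sd(lx))
      list(c(b0, mean(x)), c(1, mean(x)), c(2, mean(x)))
    }),
  inverse_weibull = list(
    par_names = c("beta", "lambda"),
    lpdf = function(x, b, l)
      log(b) + b * log(l) - (b + 1) * log(x) - (l / x)^b,
    cdf = function(x, b, l) exp(-(l / x)^b),
    starts = function(x) {
      lx <- log(x)
      b0 <- max(0.1, 1.2 / stats::sd(lx))
      list(c(b0, exp(mean(lx))), c(1, stats::median(x)), c(2, stats::median(x)))
    }),
  lomax = list(
    par_names = c("beta", "lambda"),
    lpdf = function(x, b, l) log(b) - log(l) - (b + 1) * log1p(x / l),
    cdf = function(x, b, l) 1 - (1 + x / l)^(-b),
    starts = function(x)
      list(c(2, mean(x)), c(1, stats::median(x)), c(10, 10 * mean(x)),
           c(100, 100 * mean(x)))))

#' Goodness-of-fit statistics against a fitted cdf
#'
#' One-sample Kolmogorov-Smirnov, Cramér-von Mises and Anderson-Darling
#' statistics of a sample against an arbitrary continuous cdf, with the
#' asymptotic Kolmogorov p-value for the KS distance.
#'
#' The statistics use the classical (uncorrected) definitions on the
#' sorted sample \eqn{x_{(1)} \le \dots \le x_{(n)}}:
#' \deqn{D = \max_i \max\{i/n - F(x_{(i)}),\; F(x_{(i)}) - (i-1)/n\},}
#' \deqn{W^2 = \frac{1}{12n} + \sum_i \left(F(x_{(i)}) -
#'   \frac{2i-1}{2n}\right)^2,}
#' \deqn{A^2 = -n - \frac{1}{n}\sum_i (2i-1)\left[\ln F(x_{(i)}) +
#'   \ln(1 - F(x_{(n+1-i)}))\right].}
#' Small-sample corrected variants (multiplying \eqn{W^2} by
#' \eqn{1 + 1/(2n)} and \eqn{A^2} by \eqn{1 + 0.75/n + 2.25/n^2}) are
#' returned when `corrected = TRUE`.
#'
#' The p-value uses the asymptotic Kolmogorov distribution of
#' \eqn{\sqrt{n} D} even though the cdf is usually fitted to the same
#' data; it is therefore not calibration-valid for composite hypotheses
#' and a warning says so once per session.
#'
#' @param x sample of strictly positive values.
#' @param cdf a vectorised distribution function.
#' @param corrected logical; also apply the small-sample corrections.
#' @return A list of class `pml_gof` with elements `ks_d`, `ks_p`, `cvm`,
#'   `ad`, `n` (and `cvm_corrected`, `ad_corrected` if requested).
#' @export
gof_test <- function(x, cdf, corrected = FALSE) {
  .check_sample(x)
  xs <- sort(x)
  n <- length(xs)
  Fi <- cdf(xs)
  if (any(Fi <= 0 | Fi >= 1)) {
    warning("fitted cdf reached 0 or 1 at a data point; clamping to [1e-15, 1 - 1e-15]")
    Fi <- pmin(pmax(Fi, 1e-15), 1 - 1e-15)
  }
  i <- seq_len(n)
  ks_d <- max(pmax(i / n - Fi, Fi - (i - 1) / n))
  cvm <- 1 / (12 * n) + sum((Fi - (2 * i - 1) / (2 * n))^2)
  ad <- -n - mean((2 * i - 1) * (log(Fi) + log(1 - rev(Fi))))
  out <- list(ks_d = ks_d, ks_p = .kolmogorov_pvalue(sqrt(n) * ks_d),
              cvm = cvm, ad = ad, n = n)
  if (corrected) {
    out$cvm_corrected <- cvm * (1 + 0.5 / n)
    out$ad_corrected <- ad * (1 + 0.75 / n + 2.25 / n^2)
  }
  structure(out, class = "pml_gof")
}

# P(K > t) for the asymptotic Kolmogorov distribution
.kolmogorov_pvalue <- function(t) {
  if (t < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' @export
print.pml_gof <- function(x, digits = 4, ...) {
  cat(sprintf("KS D = %.*f (p = %.*f)  CvM = %.*f  AD = %.*f  [n = %d]\n",
              digits, x$ks_d, digits, x$ks_p, digits, x$cvm, digits, x$ad,
              x$n))
  invisible(x)
}

#' Fit and compare several lifetime families on one sample
#'
#' Fits each requested family by maximum likelihood and evaluates the
#' goodness-of-fit statistics of [gof_test()] against each fitted cdf.
#' Families whose fit fails are reported with `NA` rows rather than
#' raising an error.
#'
#' @param x sample of strictly positive values.
#' @param families character vector of family names: `"pml"` plus any of
#'   the [fit_comparator()] families.
#' @return A [tibble::tibble()] with one row per parameter per family:
#'   family, term, estimate, se, and the model-level loglik, ks_d, ks_p,
#'   cvm, ad columns repeated within a family.
#' @export
compare_models <- function(x, families = c("pml", "power_lindley")) {
  stopifnot(length(families) >= 1)
  rows <- lapply(families, function(fam) {
    fit <- if (fam == "pml") fit_pml(x) else fit_comparator(x, fam)
    if (!isTRUE(fit$converged) && all(is.na(fit$estimate))) {
      return(tibble::tibble(family = fam, term = NA_character_,
                            estimate = NA_real_, se = NA_real_,
                            loglik = NA_real_, ks_d = NA_real_,
                            ks_p = NA_real_, cvm = NA_real_, ad = NA_real_))
    }
    g <- gof_test(x, fitted_cdf(fit))
    tibble::tibble(family = fam, term = names(fit$estimate),
                   estimate = unname(fit$estimate), se = unname(fit$se),
                   loglik = fit$loglik, ks_d = g$ks_d, ks_p = g$ks_p,
                   cvm = g$cvm, ad = g$ad)
  })
  do.call(rbind, rows)
}
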