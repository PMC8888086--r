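#' Trace and marginal-density diagnostics for an MCMC chain
#'
#' One row per parameter: trace of the retained draws and a histogram
#' with a kernel density overlay.  Base graphics; intended as a quick
#' convergence check.
#'
#' @param x a `pml_chain` object.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.pml_chain <- function(x, ...) {
  draws <- x$draws
  p <- ncol(draws)
  op <- graphics::par(mfrow = c(p, 2), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(p)) {
    nm <- colnames(draws)[j]
    graphics::plot(draws[, j], type = "l", main = paste("trace:", nm),
                   xlab = "", ylab = nm)
    graphics::hist(draws[, j], freq = FALSE, main = paste("posterior:", nm),
                   xlab = nm, ...)
    graphics::lines(stats::density(draws[, j]))
  }
  invisible(x)
}
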