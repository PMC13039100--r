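#' Monte Carlo outcome measures
#'
#' The four measures used to summarize a simulation condition across
#' replications.
#'
#' `standardized_bias` is the mean estimation error divided by the
#' empirical standard deviation of the estimates (sample, divisor
#' \eqn{n - 1}); values below 0.4 in absolute value are conventionally
#' considered acceptable. `mean_squared_error` is the average squared
#' estimation error. `ci_coverage` is the fraction of intervals (closed
#' endpoints) containing the truth; nominal 95% coverage is expected to
#' exceed 0.90, with (0.925, 0.975) as the liberal acceptance band.
#' `rejection_rate` is the fraction of p-values below `alpha`: the Type I
#' error rate when the analysis model is correct, power when it is
#' misspecified.
#'
#' @param estimates Numeric vector of per-replication estimates.
#' @param truth Population value.
#' @return A scalar; `standardized_bias`, `ci_coverage` and
#'   `rejection_rate` carry their conventional acceptability bands as a
#'   `"band"` attribute.
#' @export
standardized_bias <- function(estimates, truth) {
  if (length(estimates) < 2) stop("need at least 2 replications")
  s <- stats::sd(estimates)
  if (s == 0) stop("zero standard deviation across replications")
  structure((mean(estimates) - truth) / s, band = c(-0.4, 0.4))
}

#' @rdname standardized_bias
#' @export
mean_squared_error <- function(estimates, truth) {
  if (length(estimates) < 1) stop("need at least 1 replication")
  mean((estimates - truth)^2)
}

#' @param lower,upper Per-replication interval endpoints.
#' @rdname standardized_bias
#' @export
ci_coverage <- function(lower, upper, truth) {
  if (length(lower) != length(upper)) stop("endpoint lengths differ")
  if (length(lower) < 1) stop("need at least 1 replication")
  structure(mean(lower <= truth & truth <= upper),
            band = c(0.925, 0.975), floor = 0.90)
}

#' @param p_values Per-replication p-values.
#' @param alpha Significance level (default 0.05).
#' @rdname standardized_bias
#' @export
rejection_rate <- function(p_values, alpha = 0.05) {
  if (length(p_values) < 1) stop("need at least 1 replication")
  structure(mean(p_values < alpha), band = c(0.025, 0.075))
}
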