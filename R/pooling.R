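#' Pool estimates and variances with Rubin's rules
#'
#' Combines per-imputation point estimates and squared standard errors:
#' \eqn{\bar\theta} is the arithmetic mean of the estimates,
#' \eqn{V_W} the mean within-imputation variance,
#' \eqn{V_B} the between-imputation variance (divisor \eqn{m - 1}), and
#' \eqn{V_{pooled} = V_W + V_B + V_B / m}. Intervals use a t reference whose
#' degrees of freedom follow either the Barnard--Rubin small-sample
#' adjustment (default) or the classical large-sample formula.
#'
#' @param estimates An `m` by `p` matrix (or list of named vectors) of
#'   per-imputation estimates.
#' @param variances Matching matrix/list of squared standard errors.
#' @param level Confidence level for the pooled intervals.
#' @param df_complete Complete-data degrees of freedom used by the
#'   Barnard--Rubin adjustment (typically `n - npar`); `Inf` disables the
#'   small-sample component.
#' @param small_sample Use the Barnard--Rubin df (default `TRUE`); otherwise
#'   the classical \eqn{(m-1)(1 + 1/r)^2} df.
#' @return Object of class `pooled_estimates` with `estimates`,
#'   `within_var`, `between_var`, `total_var`, `df` and an `intervals` data
#'   frame.
#' @export
pool_rubin <- function(estimates, variances, level = 0.95,
                       df_complete = Inf, small_sample = TRUE) {
  if (is.list(estimates)) estimates <- do.call(rbind, estimates)
  if (is.list(variances)) variances <- do.call(rbind, variances)
  m <- nrow(estimates)
  if (m < 2) stop("Rubin pooling needs at least 2 imputations")
  if (!all(dim(estimates) == dim(variances)))
    stop("`estimates` and `variances` must have the same shape")
  qbar <- colMeans(estimates)
  VW <- colMeans(variances)
  VB <- apply(estimates, 2L, stats::var)
  Vp <- VW + VB + VB / m

  lambda <- pmin(pmax((VB + VB / m) / Vp, 1e-12), 1)
  df_old <- (m - 1) / lambda^2
  if (small_sample && is.finite(df_complete)) {
    df_obs <- (df_complete + 1) / (df_complete + 3) * df_complete *
      (1 - lambda)
    df <- 1 / (1 / df_old + 1 / df_obs)
  } else {
    df <- df_old
  }
  tq <- stats::qt((1 + level) / 2, df)
  intervals <- data.frame(parameter = colnames(estimates),
                          estimate = unname(qbar),
                          se = sqrt(unname(Vp)),
                          df = unname(df),
                          lower = unname(qbar - tq * sqrt(Vp)),
                          upper = unname(qbar + tq * sqrt(Vp)),
                          row.names = NULL)
  structure(list(estimates = qbar, within_var = VW, between_var = VB,
                 total_var = Vp, df = df, m = m, intervals = intervals),
            class = "pooled_estimates")
}

new_pooled_test <- function(name, statistic, ariv, df1, df2, p_value) {
  structure(list(name = name, statistic = statistic, ariv = ariv,
                 df1 = as.integer(df1), df2 = df2, p_value = p_value),
            class = "pooled_test")
}

#' @export
print.pooled_test <- function(x, ...) {
  cat(sprintf("%s = %.4f, ARIV = %.4f, F(%d, %s), p = %.4g\n", x$name,
              x$statistic, x$ariv, x$df1,
              if (is.finite(x$df2)) sprintf("%.1f", x$df2) else "Inf",
              x$p_value))
  invisible(x)
}

#' D2: pooling of per-imputation test statistics
#'
#' Combines `m` likelihood-ratio (or Wald) statistics:
#' \deqn{D_2 = \frac{\bar T / k - \frac{m+1}{m-1} r_2}{1 + r_2},}
#' with \eqn{r_2 = (1 + 1/m)\,\mathrm{var}(\sqrt{T_i})} the estimated
#' average relative increase in variance, referred to an
#' \eqn{F(k, \nu_2)} distribution with
#' \eqn{\nu_2 = k^{-3/m}(m-1)(1 + 1/r_2)^2}. With zero
#' between-imputation spread the statistic degenerates to \eqn{\bar T / k}
#' against \eqn{\chi^2_k / k}.
#'
#' @param statistics Numeric vector of `m` nonnegative test statistics.
#' @param k Degrees of freedom of the underlying test.
#' @return A `pooled_test`.
#' @export
pool_d2 <- function(statistics, k) {
  statistics <- as.numeric(statistics)
  m <- length(statistics)
  if (m < 2) stop("need at least 2 statistics")
  if (any(statistics < 0)) stop("test statistics must be nonnegative")
  Tbar <- mean(statistics)
  ariv <- (1 + 1 / m) * stats::var(sqrt(statistics))
  if (ariv <= 0) {
    D2 <- Tbar / k
    return(new_pooled_test("D2", D2, 0, k, Inf,
                           stats::pchisq(Tbar, k, lower.tail = FALSE)))
  }
  D2 <- (Tbar / k - (m + 1) / (m - 1) * ariv) / (1 + ariv)
  nu2 <- k^(-3 / m) * (m - 1) * (1 + 1 / ariv)^2
  p <- if (D2 <= 0) 1 else stats::pf(D2, k, nu2, lower.tail = FALSE)
  new_pooled_test("D2", D2, ariv, k, nu2, p)
}

# F-denominator df shared by D3 and D4 (large/small k(m-1) branching).
d3_denominator_df <- function(k, m, ariv) {
  a <- k * (m - 1)
  if (ariv <= 0) return(Inf)
  if (a > 4) 4 + (a - 4) * (1 + (1 - 2 / a) / ariv)^2
  else a * (1 + 1 / k) * (1 + 1 / ariv)^2 / 2
}

# Complete-data log-likelihood of one dataset's sufficient statistics at
# fixed moments.
complete_loglik_at <- function(ybar, C, n, mu, Sigma) {
  T_occ <- length(mu)
  R <- chol(Sigma)
  Sinv <- chol2inv(R)
  d <- ybar - mu
  -n / 2 * (T_occ * log(2 * pi) + 2 * sum(log(diag(R))) +
              sum(Sinv * C) + drop(crossprod(d, Sinv %*% d)))
}

dataset_suffstats <- function(Y) {
  n <- nrow(Y)
  ybar <- colMeans(Y)
  C <- crossprod(sweep(Y, 2L, ybar)) / n
  list(ybar = ybar, C = (C + t(C)) / 2, n = n)
}

#' D3: pooling by likelihood re-evaluation at pooled parameter values
#'
#' Averages the per-imputation LRT statistics (\eqn{\bar T_{LR}}), then
#' re-evaluates (without refitting) both the growth model at the
#' Rubin-pooled growth parameters and the saturated model at the averaged
#' moment estimates on every imputed dataset to obtain
#' \eqn{\bar T_{Constrained}}. The pooled statistic is
#' \deqn{D_3 = \frac{\bar T_{Constrained}}{k (1 + r_3)}, \quad
#'   r_3 = \frac{m + 1}{k (m - 1)} (\bar T_{LR} - \bar T_{Constrained}),}
#' referred to \eqn{F(k, \nu)} with the standard denominator-df branching.
#' \eqn{D_3} can be negative; it is reported as-is with a warning.
#'
#' @param imputations An `imputation_set` of completed datasets.
#' @param spec Analysis-model [growth_spec()].
#' @param fits List of `m` converged [fit_growth()] results, one per
#'   imputed dataset (fitted with the same `spec`).
#' @param saturated_fits List of `m` [fit_saturated()] results.
#' @param k LRT degrees of freedom; default [lrt_df()] of `spec`.
#' @return A `pooled_test`.
#' @export
pool_d3 <- function(imputations, spec, fits, saturated_fits, k = NULL) {
  stopifnot(inherits(imputations, "imputation_set"))
  m <- imputations$m
  if (m < 2) stop("D3 needs at least 2 imputations")
  if (is.null(k)) k <- lrt_df(spec)
  T_i <- mapply(function(f, s) max(-2 * (f$loglik - s$loglik), 0),
                fits, saturated_fits)
  Tbar_LR <- mean(T_i)

  est <- do.call(rbind, lapply(fits, `[[`, "estimates"))
  pooled_est <- colMeans(est)
  Lam <- loading_matrix(spec)
  pooled_mom <- moments_from_natural(pooled_est, spec, Lam)
  mu_sat <- Reduce(`+`, lapply(saturated_fits, `[[`, "mean")) / m
  Sig_sat <- Reduce(`+`, lapply(saturated_fits, `[[`, "cov")) / m

  Tcon <- vapply(imputations$datasets, function(Y) {
    ss <- dataset_suffstats(Y)
    lg <- complete_loglik_at(ss$ybar, ss$C, ss$n, pooled_mom$mean,
                             pooled_mom$cov)
    ls <- complete_loglik_at(ss$ybar, ss$C, ss$n, mu_sat, Sig_sat)
    -2 * (lg - ls)
  }, numeric(1))
  Tbar_con <- mean(Tcon)

  ariv <- (m + 1) / (k * (m - 1)) * (Tbar_LR - Tbar_con)
  D3 <- Tbar_con / (k * (1 + ariv))
  if (D3 < 0)
    warning("negative D3 statistic (", format(D3), "); reported as-is")
  nu <- d3_denominator_df(k, m, ariv)
  p <- if (D3 <= 0) 1
  else if (is.finite(nu)) stats::pf(D3, k, nu, lower.tail = FALSE)
  else stats::pchisq(k * D3, k, lower.tail = FALSE)
  out <- new_pooled_test("D3", D3, ariv, k, nu, p)
  out$Tbar_LR <- Tbar_LR
  out$Tbar_constrained <- Tbar_con
  out
}

#' D4: pooling via the stacked-data likelihood ratio
#'
#' Stacks the `m` imputed datasets into one `m * n`-row table, fits the
#' growth and saturated models to the stack by complete-data ML, and forms
#' \eqn{\bar T_{Stacked} = T_{stacked} / m}. The pooled statistic is
#' \deqn{D_4 = \frac{\bar T_{Stacked}}{k\,[1 + \max(r_4, 0)]}, \quad
#'   r_4 = \frac{m + 1}{k (m - 1)} (\bar T_{LR} - \bar T_{Stacked}),}
#' guaranteed nonnegative, with the same F-denominator df as D3.
#'
#' @inheritParams pool_d3
#' @param fits Optional list of per-imputation growth fits used for
#'   \eqn{\bar T_{LR}}; alternatively supply `statistics`.
#' @param statistics Optional numeric vector of per-imputation LRT
#'   statistics (used when `fits`/`saturated_fits` are not given).
#' @return A `pooled_test`.
#' @export
pool_d4 <- function(imputations, spec, fits = NULL, saturated_fits = NULL,
                    statistics = NULL, k = NULL) {
  stopifnot(inherits(imputations, "imputation_set"))
  m <- imputations$m
  if (m < 2) stop("D4 needs at least 2 imputations")
  if (is.null(k)) k <- lrt_df(spec)
  if (is.null(statistics)) {
    if (is.null(fits) || is.null(saturated_fits))
      stop("supply either `statistics` or `fits` + `saturated_fits`")
    statistics <- mapply(function(f, s)
      max(-2 * (f$loglik - s$loglik), 0), fits, saturated_fits)
  }
  Tbar_LR <- mean(statistics)

  stacked <- do.call(rbind, imputations$datasets)
  sat_stacked <- fit_saturated(stacked)
  fit_stacked <- fit_growth(stacked, spec, se = FALSE,
                            start = list(mean = sat_stacked$mean,
                                         cov = sat_stacked$cov))
  if (!fit_stacked$converged) stop("stacked growth fit did not converge")
  T_stacked <- max(-2 * (fit_stacked$loglik - sat_stacked$loglik), 0)
  Tbar_stacked <- T_stacked / m

  ariv <- (m + 1) / (k * (m - 1)) * (Tbar_LR - Tbar_stacked)
  ariv_pos <- max(ariv, 0)
  D4 <- Tbar_stacked / (k * (1 + ariv_pos))
  nu <- d3_denominator_df(k, m, ariv_pos)
  p <- if (is.finite(nu)) stats::pf(D4, k, nu, lower.tail = FALSE)
  else stats::pchisq(k * D4, k, lower.tail = FALSE)
  out <- new_pooled_test("D4", D4, ariv, k, nu, p)
  out$Tbar_LR <- Tbar_LR
  out$Tbar_stacked <- Tbar_stacked
  out
}
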