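#' @keywords internal
as_outcome_matrix <- function(data) {
  if (inherits(data, "incomplete_data")) data <- data$values
  Y <- as.matrix(data)
  storage.mode(Y) <- "double"
  Y
}

# Group rows by missingness pattern and keep per-pattern sufficient
# statistics: observed indices, count, mean vector, and the ML (divisor n)
# scatter matrix of the observed sub-vectors. Rows with no observed entries
# contribute nothing to the likelihood and are dropped with a warning.
pattern_stats <- function(Y) {
  Y <- as_outcome_matrix(Y)
  T_occ <- ncol(Y)
  obs <- !is.na(Y)
  none <- rowSums(obs) == 0L
  if (any(none)) {
    warning(sum(none), " rows with no observed entries dropped")
    Y <- Y[!none, , drop = FALSE]
    obs <- obs[!none, , drop = FALSE]
  }
  key <- drop(obs %*% 2^(seq_len(T_occ) - 1))
  groups <- split(seq_along(key), key)
  stats <- lapply(groups, function(idx) {
    o <- which(obs[idx[1], ])
    Yg <- Y[idx, o, drop = FALSE]
    n <- length(idx)
    ybar <- colMeans(Yg)
    C <- crossprod(Yg) / n - tcrossprod(ybar)
    list(o = o, n = n, ybar = ybar, C = (C + t(C)) / 2)
  })
  attr(stats, "n_used") <- nrow(Y)
  attr(stats, "n_occasions") <- T_occ
  stats
}

loglik_from_stats <- function(stats, mu, Sigma) {
  ll <- 0
  for (g in stats) {
    o <- g$o
    R <- tryCatch(chol(Sigma[o, o, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(R)) return(NA_real_)
    Sinv <- chol2inv(R)
    d <- g$ybar - mu[o]
    quad <- sum(Sinv * g$C) + drop(crossprod(d, Sinv %*% d))
    ll <- ll + g$n *
      (-0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(R))) + quad))
  }
  ll
}

# Gradient of loglik_from_stats with respect to mu and Sigma (full-matrix
# convention): per pattern, d ll / d mu_o = n Sinv d and
# d ll / d Sigma_oo = n/2 [Sinv (C + d d') Sinv - Sinv]. Returns NULL when
# an observed sub-covariance is singular (the objective is 1e10 there).
loglik_grad_from_stats <- function(stats, mu, Sigma) {
  T_occ <- length(mu)
  gmu <- numeric(T_occ)
  GS <- matrix(0, T_occ, T_occ)
  for (g in stats) {
    o <- g$o
    R <- tryCatch(chol(Sigma[o, o, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Sinv <- chol2inv(R)
    d <- g$ybar - mu[o]
    gmu[o] <- gmu[o] + g$n * drop(Sinv %*% d)
    S <- g$C + tcrossprod(d)
    GS[o, o] <- GS[o, o] + (g$n / 2) * (Sinv %*% S %*% Sinv - Sinv)
  }
  list(gmu = gmu, GSigma = GS)
}

#' Observed-data log-likelihood under given moments
#'
#' Evaluates the multivariate-normal log-likelihood of a (possibly
#' incomplete) wide dataset at a fixed mean vector and covariance matrix:
#' each row contributes the log-density of its observed sub-vector under the
#' corresponding sub-mean and sub-covariance. Rows with no observed entries
#' contribute zero.
#'
#' @param data Numeric matrix with `NA` for missing cells, or an
#'   `incomplete_data` object.
#' @param mean Mean vector of length `ncol(data)`.
#' @param cov Covariance matrix; any required observed sub-matrix must be
#'   nonsingular.
#' @return The log-likelihood (scalar).
#' @export
pattern_loglik <- function(data, mean, cov) {
  if (inherits(mean, "moment_structure")) {
    cov <- mean$cov
    mean <- mean$mean
  }
  st <- pattern_stats(data)
  ll <- loglik_from_stats(st, mean, cov)
  if (is.na(ll)) stop("singular observed sub-covariance")
  ll
}

# --- parameter transforms ---------------------------------------------------

# Optimization parameterization: factor means free; Psi = L L' with L lower
# triangular and L[i, 1] zeroed for each fixed intercept--factor covariance;
# residual variances on the log scale. Keeps Sigma PD without constraints.
growth_parmap <- function(spec) {
  q <- spec$n_factors
  fz <- spec$fixed_zero
  Lidx <- which(lower.tri(matrix(0, q, q), diag = TRUE), arr.ind = TRUE)
  if (nrow(fz)) {
    drop_rows <- logical(nrow(Lidx))
    for (r in seq_len(nrow(fz))) {
      a <- fz[r, 1]; b <- fz[r, 2]
      if (a != 1L)
        stop("fixed-zero covariances are supported only for pairs that ",
             "include the intercept factor")
      drop_rows <- drop_rows | (Lidx[, 1] == b & Lidx[, 2] == 1L)
    }
    Lidx <- Lidx[!drop_rows, , drop = FALSE]
  }
  list(q = q, T_occ = spec$n_occasions, Lidx = Lidx,
       npar = q + nrow(Lidx) + spec$n_occasions)
}

unpack_growth_par <- function(par, map) {
  q <- map$q
  alpha <- par[seq_len(q)]
  L <- matrix(0, q, q)
  L[map$Lidx] <- par[q + seq_len(nrow(map$Lidx))]
  theta <- exp(par[q + nrow(map$Lidx) + seq_len(map$T_occ)])
  list(alpha = alpha, Psi = tcrossprod(L), theta = theta, L = L)
}

growth_start_values <- function(mu0, Sigma0, spec, map) {
  Lam <- loading_matrix(spec)
  P <- solve(crossprod(Lam), t(Lam))
  alpha0 <- drop(P %*% mu0)
  dS <- diag(Sigma0)
  theta0 <- pmax(0.2 * dS, 1e-4)
  for (i in 1:2) {
    Psi0 <- P %*% (Sigma0 - diag(theta0, map$T_occ)) %*% t(P)
    resid <- dS - diag(Lam %*% Psi0 %*% t(Lam))
    theta0 <- pmax(resid, 0.02 * dS)
  }
  ev <- eigen((Psi0 + t(Psi0)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-3 * max(ev$values, 1e-4))
  Psi0 <- ev$vectors %*% (lam * t(ev$vectors))
  if (nrow(spec$fixed_zero))
    for (r in seq_len(nrow(spec$fixed_zero))) {
      a <- spec$fixed_zero[r, 1]; b <- spec$fixed_zero[r, 2]
      Psi0[a, b] <- Psi0[b, a] <- 0
    }
  ev <- eigen((Psi0 + t(Psi0)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 0)
    Psi0 <- Psi0 + diag(abs(min(ev$values)) + 1e-4, map$q)
  L0 <- t(chol(Psi0))
  c(alpha0, L0[map$Lidx], log(theta0))
}

# --- growth model fit -------------------------------------------------------

#' Fit a latent growth curve model by (full-information) maximum likelihood
#'
#' Maximizes the observed-data log-likelihood of the growth model over the
#' free parameters: factor means, the free elements of the factor covariance
#' matrix (any fixed-zero covariances are imposed by construction through a
#' zeroed Cholesky entry), and one residual variance per occasion. Complete
#' data reduce to ordinary ML; incomplete data are handled casewise through
#' missingness-pattern grouping, i.e. FIML.
#'
#' Standard errors are square roots of the diagonal of the inverse numerical
#' observed-information matrix, computed by central differences on the
#' natural parameter scale.
#'
#' @param data Wide outcome matrix (may contain `NA`) or `incomplete_data`.
#' @param spec A [growth_spec()].
#' @param start Optional starting values: a list with `mean` and `cov`
#'   moment estimates used to initialize the free parameters (e.g. from a
#'   saturated fit). Defaults to moments estimated from the data.
#' @param se Compute standard errors (default `TRUE`). Skipping them speeds
#'   up large Monte Carlo runs that only need point estimates or test
#'   statistics.
#' @param control Passed to [stats::optim()] (method `"BFGS"`).
#' @return Object of class `growth_fit`: named `estimates`, `se`, `loglik`,
#'   `converged`, `n_used`, `npar`, `model_label = "growth"` and the `spec`.
#' @export
fit_growth <- function(data, spec, start = NULL, se = TRUE,
                       control = list(maxit = 500, reltol = 1e-9)) {
  stopifnot(inherits(spec, "growth_spec"))
  st <- pattern_stats(data)
  if (attr(st, "n_occasions") != spec$n_occasions)
    stop("data have ", attr(st, "n_occasions"),
         " occasions but the spec expects ", spec$n_occasions)
  map <- growth_parmap(spec)
  Lam <- loading_matrix(spec)

  if (is.null(start)) {
    if (length(st) == 1L && length(st[[1]]$o) == spec$n_occasions) {
      start <- list(mean = st[[1]]$ybar, cov = st[[1]]$C)
    } else {
      em <- em_mvn(data, tol = 1e-5, max_iter = 200)
      start <- list(mean = em$mean, cov = em$cov)
    }
  }
  par0 <- growth_start_values(start$mean, start$cov, spec, map)

  negll <- function(par) {
    p <- unpack_growth_par(par, map)
    Sigma <- Lam %*% p$Psi %*% t(Lam) + diag(p$theta, map$T_occ)
    ll <- loglik_from_stats(st, drop(Lam %*% p$alpha), Sigma)
    if (is.na(ll)) 1e10 else -ll
  }
  negll_grad <- function(par) {
    p <- unpack_growth_par(par, map)
    Sigma <- Lam %*% p$Psi %*% t(Lam) + diag(p$theta, map$T_occ)
    g <- loglik_grad_from_stats(st, drop(Lam %*% p$alpha), Sigma)
    if (is.null(g)) return(numeric(map$npar))
    Gpsi <- t(Lam) %*% g$GSigma %*% Lam
    c(-drop(crossprod(Lam, g$gmu)),        # alpha
      -(2 * (Gpsi %*% p$L))[map$Lidx],     # free Cholesky entries
      -diag(g$GSigma) * p$theta)           # log residual variances
  }
  opt <- stats::optim(par0, negll, gr = negll_grad, method = "BFGS",
                      control = control)
  p <- unpack_growth_par(opt$par, map)

  nm <- param_names(spec)
  est <- natural_estimates(p, spec)
  names(est) <- nm

  ses <- rep(NA_real_, length(est))
  info_ok <- TRUE
  if (se) {
    h <- se_from_information(est, st, spec, Lam)
    ses <- h$se
    info_ok <- h$ok
  }
  names(ses) <- nm

  structure(list(estimates = est, se = ses, loglik = -opt$value,
                 converged = opt$convergence == 0,
                 information_ok = info_ok,
                 n_used = attr(st, "n_used"), npar = map$npar,
                 model_label = "growth", spec = spec),
            class = "growth_fit")
}

natural_estimates <- function(p, spec) {
  q <- spec$n_factors
  est <- c(p$alpha, diag(p$Psi))
  for (a in seq_len(q - 1)) for (b in seq(a + 1, q))
    if (!pair_is_fixed(spec, a, b)) est <- c(est, p$Psi[a, b])
  c(est, p$theta)
}

# Rebuild (mu, Sigma) from the natural parameter vector (means, variances,
# free covariances, residual variances) in param_names() order.
moments_from_natural <- function(est, spec, Lam) {
  q <- spec$n_factors
  alpha <- est[seq_len(q)]
  Psi <- diag(est[q + seq_len(q)], q)
  pos <- 2L * q
  for (a in seq_len(q - 1)) for (b in seq(a + 1, q))
    if (!pair_is_fixed(spec, a, b)) {
      pos <- pos + 1L
      Psi[a, b] <- Psi[b, a] <- est[pos]
    }
  theta <- est[pos + seq_len(spec$n_occasions)]
  list(mean = drop(Lam %*% alpha),
       cov = Lam %*% Psi %*% t(Lam) + diag(theta, spec$n_occasions))
}

se_from_information <- function(est, st, spec, Lam) {
  f <- function(x) {
    m <- moments_from_natural(x, spec, Lam)
    ll <- loglik_from_stats(st, m$mean, m$cov)
    if (is.na(ll)) 1e10 else -ll
  }
  H <- tryCatch(pracma::hessian(f, est), error = function(e) NULL)
  if (is.null(H))
    return(list(se = rep(NA_real_, length(est)), ok = FALSE))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0))
    return(list(se = rep(NA_real_, length(est)), ok = FALSE))
  list(se = sqrt(diag(V)), ok = TRUE)
}

#' Fit the saturated multivariate-normal model
#'
#' Estimates an unstructured mean vector and covariance matrix by maximum
#' likelihood. With complete data this is the closed-form sample mean and
#' ML (divisor \eqn{n}) covariance; with incomplete data the EM algorithm
#' is iterated until the log-likelihood change falls below `tol`.
#'
#' @inheritParams fit_growth
#' @param tol EM convergence tolerance on the log-likelihood (default
#'   `1e-7`).
#' @param max_iter Maximum EM iterations.
#' @return Object of class `saturated_fit` with `mean`, `cov`, `loglik`,
#'   `converged`, `n_used`, `npar` and `model_label = "saturated"`.
#' @export
fit_saturated <- function(data, tol = 1e-7, max_iter = 1000) {
  Y <- as_outcome_matrix(data)
  T_occ <- ncol(Y)
  npar <- as.integer(T_occ + T_occ * (T_occ + 1) / 2)
  if (!anyNA(Y)) {
    n <- nrow(Y)
    mu <- colMeans(Y)
    S <- crossprod(sweep(Y, 2L, mu)) / n
    ll <- -n / 2 * (T_occ * log(2 * pi) +
                      determinant(S, logarithm = TRUE)$modulus[1] + T_occ)
    return(structure(list(mean = mu, cov = S, loglik = as.numeric(ll),
                          converged = TRUE, iterations = 0L,
                          n_used = n, npar = npar,
                          model_label = "saturated"),
                     class = "saturated_fit"))
  }
  em <- em_mvn(Y, tol = tol, max_iter = max_iter)
  structure(list(mean = em$mean, cov = em$cov,
                 loglik = em$loglik_trace[length(em$loglik_trace)],
                 converged = em$converged, iterations = em$iterations,
                 n_used = em$n_used, npar = npar,
                 model_label = "saturated"),
            class = "saturated_fit")
}

#' Likelihood-ratio test of a growth model against the saturated model
#'
#' Computes \eqn{T = -2[\ell(\hat\theta) - \ell(\tilde\beta)]} and refers it
#' to a chi-square distribution with `df` degrees of freedom. Tiny negative
#' statistics (within `1e-6`) from numerical round-off are clamped to zero.
#'
#' @param fit A converged [fit_growth()] result.
#' @param saturated A converged [fit_saturated()] result on the same data.
#' @param df Degrees of freedom; defaults to [lrt_df()] of the fit's spec.
#' @return List of class `lrt_result`: `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit, saturated, df = NULL) {
  if (!isTRUE(fit$converged) || !isTRUE(saturated$converged))
    stop("both fits must have converged")
  if (fit$n_used != saturated$n_used)
    stop("fits use different numbers of rows")
  if (is.null(df)) df <- lrt_df(fit$spec)
  stat <- -2 * (fit$loglik - saturated$loglik)
  if (stat < -1e-6)
    warning("negative LRT statistic (", format(stat),
            "); likely a failed optimization")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' Wald confidence intervals for fitted parameters
#'
#' Normal-theory intervals `estimate +/- z * SE` per parameter.
#'
#' @param fit A [fit_growth()] result with standard errors.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `parameter`, `estimate`, `se`, `lower`,
#'   `upper`.
#' @export
wald_intervals <- function(fit, level = 0.95) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  z <- stats::qnorm((1 + level) / 2)
  data.frame(parameter = names(fit$estimates),
             estimate = unname(fit$estimates),
             se = unname(fit$se),
             lower = unname(fit$estimates - z * fit$se),
             upper = unname(fit$estimates + z * fit$se),
             row.names = NULL)
}
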