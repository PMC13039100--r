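#' EM algorithm for the incomplete-data multivariate normal
#'
#' Maximum-likelihood estimation of an unstructured mean vector and
#' covariance matrix from data with arbitrary (ignorable) missingness.
#' The E-step computes, per missingness pattern, the conditional expectations
#' of the missing sub-vectors and their cross-products given the observed
#' entries; the M-step updates the moments from the completed sufficient
#' statistics. The log-likelihood trace is non-decreasing; iteration stops
#' when its change falls below `tol`.
#'
#' @param data Wide outcome matrix with `NA` for missing cells, or an
#'   `incomplete_data` object. Each occasion must be observed for at least
#'   one row.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum number of iterations; exceeding it flags
#'   `converged = FALSE`.
#' @return List with `mean`, `cov`, `loglik_trace`, `iterations`,
#'   `converged`, `n_used`.
#' @export
em_mvn <- function(data, tol = 1e-7, max_iter = 1000) {
  Y <- as_outcome_matrix(data)
  T_occ <- ncol(Y)
  if (any(colSums(!is.na(Y)) == 0L))
    stop("every occasion must be observed for at least one row")
  st <- pattern_stats(Y)
  N <- attr(st, "n_used")

  # raw per-pattern sums for the E-step accumulations
  raw <- lapply(st, function(g)
    list(o = g$o, n = g$n, s = g$ybar * g$n,
         S = (g$C + tcrossprod(g$ybar)) * g$n))

  mu <- vapply(seq_len(T_occ), function(j) mean(Y[, j], na.rm = TRUE),
               numeric(1))
  v <- vapply(seq_len(T_occ), function(j) stats::var(Y[, j], na.rm = TRUE),
              numeric(1))
  Sigma <- diag(pmax(v, 1e-8), T_occ)

  complete <- !anyNA(Y)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    T1 <- numeric(T_occ)
    T2 <- matrix(0, T_occ, T_occ)
    for (g in raw) {
      o <- g$o
      mi <- setdiff(seq_len(T_occ), o)
      n <- g$n
      T1[o] <- T1[o] + g$s
      T2[o, o] <- T2[o, o] + g$S
      if (length(mi)) {
        Soo_inv <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
        B <- Sigma[mi, o, drop = FALSE] %*% Soo_inv
        resid <- g$s - n * mu[o]
        a <- n * mu[mi] + drop(B %*% resid)           # E[sum y_mi]
        T1[mi] <- T1[mi] + a
        Mom <- tcrossprod(mu[mi], g$s) +
          B %*% (g$S - tcrossprod(mu[o], g$s))        # E[sum y_mi y_o']
        T2[mi, o] <- T2[mi, o] + Mom
        T2[o, mi] <- T2[o, mi] + t(Mom)
        Cm <- Sigma[mi, mi, drop = FALSE] -
          B %*% t(Sigma[mi, o, drop = FALSE])
        Smm <- n * tcrossprod(mu[mi]) +
          tcrossprod(mu[mi], drop(B %*% resid)) +
          tcrossprod(drop(B %*% resid), mu[mi]) +
          B %*% (g$S - tcrossprod(g$s, mu[o]) - tcrossprod(mu[o], g$s) +
                   n * tcrossprod(mu[o])) %*% t(B) +
          n * Cm
        T2[mi, mi] <- T2[mi, mi] + Smm
      }
    }
    mu_new <- T1 / N
    Sigma_new <- T2 / N - tcrossprod(mu_new)
    Sigma_new <- (Sigma_new + t(Sigma_new)) / 2
    ll <- loglik_from_stats(st, mu_new, Sigma_new)
    mu <- mu_new
    Sigma <- Sigma_new
    trace <- c(trace, ll)
    if (complete) { converged <- TRUE; break }
    if (it >= 2L && abs(trace[it] - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("em_mvn reached max_iter without converging")
  names(mu) <- colnames(Y)
  dimnames(Sigma) <- list(colnames(Y), colnames(Y))
  list(mean = mu, cov = Sigma, loglik_trace = trace,
       iterations = it, converged = converged, n_used = N)
}

#' @keywords internal
new_imputation_set <- function(datasets, method, meta) {
  structure(list(datasets = datasets, method = method,
                 m = length(datasets), sampler_meta = meta),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Imputation set: method %s, m = %d, %d x %d\n", x$method,
              x$m, nrow(x$datasets[[1]]), ncol(x$datasets[[1]])))
  invisible(x)
}

# Fill the missing cells of Y by a draw from the conditional normal of
# missing-given-observed under moments (mu, Sigma), pattern by pattern.
conditional_draw_fill <- function(Y, mu, Sigma) {
  out <- Y
  obs <- !is.na(Y)
  T_occ <- ncol(Y)
  key <- drop(obs %*% 2^(seq_len(T_occ) - 1))
  for (idx in split(seq_along(key), key)) {
    o <- which(obs[idx[1], ])
    mi <- setdiff(seq_len(T_occ), o)
    if (!length(mi)) next
    n <- length(idx)
    if (length(o)) {
      Soo_inv <- chol2inv(chol(Sigma[o, o, drop = FALSE]))
      B <- Sigma[mi, o, drop = FALSE] %*% Soo_inv
      cmean <- matrix(mu[mi], n, length(mi), byrow = TRUE) +
        sweep(Y[idx, o, drop = FALSE], 2L, mu[o]) %*% t(B)
      ccov <- Sigma[mi, mi, drop = FALSE] -
        B %*% t(Sigma[mi, o, drop = FALSE])
    } else {
      cmean <- matrix(mu[mi], n, length(mi), byrow = TRUE)
      ccov <- Sigma[mi, mi, drop = FALSE]
    }
    ccov <- (ccov + t(ccov)) / 2
    R <- chol(ccov + diag(1e-10, length(mi)))
    out[idx, mi] <- cmean + matrix(stats::rnorm(n * length(mi)), n) %*% R
  }
  out
}

#' Wide-format EM-with-bootstrap imputation
#'
#' For each of the `m` imputations: draw a nonparametric bootstrap resample
#' of the rows, estimate the multivariate-normal mean and covariance on the
#' resample by [em_mvn()] (this is the draw of parameter uncertainty), then
#' fill each original row's missing entries with a draw from the conditional
#' normal of missing-given-observed under those moments.
#'
#' @param data Incomplete wide matrix or `incomplete_data` object. Data with
#'   no missing cells return `m` copies of the input.
#' @param m Number of imputations.
#' @param seed Optional integer seed.
#' @param em_tol,em_max_iter EM settings for the bootstrap fits.
#' @param max_retries Bootstrap resamples in which some occasion is entirely
#'   missing are redrawn up to this many times before erroring.
#' @return An `imputation_set` with `method = "wEMB"`.
#' @export
impute_emb <- function(data, m, seed = NULL, em_tol = 1e-5,
                       em_max_iter = 300, max_retries = 25) {
  Y <- as_outcome_matrix(data)
  if (!is.null(seed)) set.seed(seed)
  meta <- list(seed = seed, em_tol = em_tol)
  if (!anyNA(Y))
    return(new_imputation_set(replicate(m, Y, simplify = FALSE),
                              "wEMB", meta))
  n <- nrow(Y)
  datasets <- vector("list", m)
  for (b in seq_len(m)) {
    for (try in seq_len(max_retries)) {
      idx <- sample.int(n, n, replace = TRUE)
      Yb <- Y[idx, , drop = FALSE]
      if (all(colSums(!is.na(Yb)) >= 2L)) break
      if (try == max_retries)
        stop("could not draw a bootstrap resample with all occasions observed")
    }
    em <- em_mvn(Yb, tol = em_tol, max_iter = em_max_iter)
    datasets[[b]] <- conditional_draw_fill(Y, em$mean, em$cov)
  }
  new_imputation_set(datasets, "wEMB", meta)
}

#' Wide-format fully conditional specification (chained equations)
#'
#' Gibbs-style chained-equations imputation: each incomplete occasion is
#' regressed on all other occasions with a Bayesian normal linear model
#' (diffuse Jeffreys-type priors, ridge-stabilized when near-collinear);
#' regression coefficients and the residual variance are drawn from their
#' conjugate posterior and the missing values from the posterior predictive.
#' Columns are visited round-robin within each iteration. The `m`
#' imputations are equally spaced post-burn-in states of the chain.
#'
#' @inheritParams impute_emb
#' @param iterations Total chain length (default 10000).
#' @param burn_in Burn-in iterations (default 5000); `iterations - burn_in`
#'   must be at least `m`.
#' @param ridge Ridge constant (relative to the predictor cross-product
#'   diagonal) stabilizing the posterior draw.
#' @return An `imputation_set` with `method = "wFCS"`.
#' @export
impute_fcs <- function(data, m, iterations = 10000, burn_in = 5000,
                       seed = NULL, ridge = 1e-5) {
  Y <- as_outcome_matrix(data)
  if (!is.null(seed)) set.seed(seed)
  meta <- list(iterations = iterations, burn_in = burn_in, seed = seed)
  if (!anyNA(Y))
    return(new_imputation_set(replicate(m, Y, simplify = FALSE),
                              "wFCS", meta))
  if (iterations - burn_in < m)
    stop("need at least m post-burn-in iterations")
  T_occ <- ncol(Y)
  miss <- is.na(Y)
  incomplete_cols <- which(colSums(miss) > 0L)

  # initialize by observed-margin mean plus residual-scaled noise
  Ycur <- Y
  for (j in incomplete_cols) {
    mj <- mean(Y[, j], na.rm = TRUE)
    sj <- stats::sd(Y[, j], na.rm = TRUE)
    k <- sum(miss[, j])
    Ycur[miss[, j], j] <- mj + stats::rnorm(k, 0, sj)
  }

  thin <- (iterations - burn_in) / m
  keep_at <- burn_in + ceiling(seq_len(m) * thin)
  datasets <- vector("list", m)
  kept <- 0L
  for (it in seq_len(iterations)) {
    for (j in incomplete_cols) {
      obs_j <- !miss[, j]
      X <- cbind(1, Ycur[, -j, drop = FALSE])
      Xo <- X[obs_j, , drop = FALSE]
      yo <- Ycur[obs_j, j]
      XtX <- crossprod(Xo)
      XtX_r <- XtX + ridge * mean(diag(XtX)) * diag(ncol(Xo))
      bhat <- solve(XtX_r, crossprod(Xo, yo))
      res <- yo - drop(Xo %*% bhat)
      df_res <- max(length(yo) - ncol(Xo), 2L)
      sigma2 <- sum(res^2) / stats::rchisq(1L, df_res)
      Rchol <- chol(solve(XtX_r))
      beta <- drop(bhat) +
        sqrt(sigma2) * drop(stats::rnorm(ncol(Xo)) %*% Rchol)
      Xm <- X[miss[, j], , drop = FALSE]
      Ycur[miss[, j], j] <- drop(Xm %*% beta) +
        stats::rnorm(nrow(Xm), 0, sqrt(sigma2))
    }
    if (kept < m && it == keep_at[kept + 1L]) {
      kept <- kept + 1L
      datasets[[kept]] <- Ycur
    }
  }
  new_imputation_set(datasets, "wFCS", meta)
}

#' Long-format multilevel model-based imputation
#'
#' Joint-model imputation for repeated measures: a multilevel growth curve
#' model \eqn{y_{ij} = x_j^\top \beta + x_j^\top u_i + e_{ij}} with
#' \eqn{x_j = (1, t_j)} (linear) or \eqn{(1, t_j, t_j^2)} (quadratic),
#' random coefficients \eqn{u_i \sim N(0, \Omega)} and residuals
#' \eqn{e_{ij} \sim N(0, \sigma^2)}, sampled by a conjugate Gibbs sampler:
#' normal full conditionals for \eqn{\beta} (flat prior) and the \eqn{u_i},
#' inverse-Wishart(\eqn{q+1}, I) for \eqn{\Omega}, inverse-gamma(0.001,
#' 0.001) for \eqn{\sigma^2}. Missing outcomes are drawn from their
#' conditional posterior predictive at every iteration; the `m` imputations
#' are equally spaced post-burn-in states, returned in wide format keyed by
#' (id, occasion).
#'
#' @param data Incomplete wide matrix (`NA` markers) or `incomplete_data`
#'   object; long-format input is accepted as a data frame with columns
#'   `id`, `occasion`, `time`, `y`.
#' @param time_codes Time codes \eqn{t_j}; required for wide input.
#' @param form `"linear"` or `"quadratic"` imputation trajectory.
#' @inheritParams impute_fcs
#' @return An `imputation_set` with `method = "llMLM"` or `"lqMLM"`.
#' @export
impute_mlm <- function(data, time_codes = NULL,
                       form = c("linear", "quadratic"), m,
                       iterations = 10000, burn_in = 5000, seed = NULL) {
  form <- match.arg(form)
  if (is.data.frame(data) && all(c("id", "occasion", "y") %in% names(data))) {
    if (is.null(time_codes) && "time" %in% names(data))
      time_codes <- unique(data[order(data$occasion), "time"])
    data <- long_to_wide(data)
  }
  Y <- as_outcome_matrix(data)
  if (is.null(time_codes)) stop("`time_codes` must be supplied")
  T_occ <- ncol(Y)
  if (length(time_codes) != T_occ)
    stop("`time_codes` length must equal the number of occasions")
  if (!is.null(seed)) set.seed(seed)
  method <- if (form == "linear") "llMLM" else "lqMLM"
  meta <- list(iterations = iterations, burn_in = burn_in, seed = seed,
               form = form)
  if (!anyNA(Y))
    return(new_imputation_set(replicate(m, Y, simplify = FALSE),
                              method, meta))
  if (iterations - burn_in < m)
    stop("need at least m post-burn-in iterations")
  if (any(rowSums(!is.na(Y)) == 0L))
    stop("every person needs at least one observed outcome")

  q <- if (form == "linear") 2L else 3L
  X <- outer(time_codes, 0:(q - 1L), `^`)          # T x q, shared design
  XtX <- crossprod(X)
  n <- nrow(Y)
  miss <- is.na(Y)

  # initial values: column-mean fill, pooled OLS slope, unit Omega
  Ycur <- Y
  for (j in seq_len(T_occ))
    if (any(miss[, j])) Ycur[miss[, j], j] <- mean(Y[, j], na.rm = TRUE)
  beta <- drop(solve(XtX, crossprod(X, colMeans(Ycur))))
  U <- matrix(0, n, q)
  sigma2 <- max(mean((Ycur - tcrossprod(rep(1, n), drop(X %*% beta)))^2),
                1e-6)
  Omega <- diag(q)
  nu0 <- q + 1
  S0 <- diag(q)
  a0 <- b0 <- 0.001
  n_cells <- n * T_occ

  thin <- (iterations - burn_in) / m
  keep_at <- burn_in + ceiling(seq_len(m) * thin)
  datasets <- vector("list", m)
  kept <- 0L
  for (it in seq_len(iterations)) {
    # 1. missing outcomes | parameters
    Fit <- (U + matrix(beta, n, q, byrow = TRUE)) %*% t(X)
    Ycur[miss] <- Fit[miss] + stats::rnorm(sum(miss), 0, sqrt(sigma2))

    # 2. random coefficients u_i (shared posterior precision, balanced design)
    Oinv <- chol2inv(chol(Omega))
    A <- XtX / sigma2 + Oinv
    Ainv <- chol2inv(chol(A))
    Yc <- Ycur - tcrossprod(rep(1, n), drop(X %*% beta))
    Umean <- (Yc %*% X %*% Ainv) / sigma2
    U <- Umean + matrix(stats::rnorm(n * q), n) %*% chol(Ainv)

    # 3. fixed effects beta (flat prior)
    resp <- Ycur - U %*% t(X)
    bhat <- solve(XtX, crossprod(X, colSums(resp))) / n
    Vb <- sigma2 * solve(XtX) / n
    beta <- drop(bhat) + drop(stats::rnorm(q) %*% chol(Vb))

    # 4. residual variance
    E <- Ycur - (U + matrix(beta, n, q, byrow = TRUE)) %*% t(X)
    sigma2 <- (b0 + sum(E^2) / 2) / stats::rgamma(1, a0 + n_cells / 2)

    # 5. random-effect covariance (inverse-Wishart)
    Sn <- S0 + crossprod(U)
    Omega <- draw_inv_wishart(nu0 + n, Sn, q)

    if (kept < m && it == keep_at[kept + 1L]) {
      kept <- kept + 1L
      datasets[[kept]] <- Ycur
    }
  }
  new_imputation_set(datasets, method, meta)
}

draw_inv_wishart <- function(df, S, q, max_jitter = 5) {
  for (k in 0:max_jitter) {
    Sj <- S + diag(k * 1e-6 * mean(diag(S)), q)
    W <- tryCatch(stats::rWishart(1, df, chol2inv(chol(Sj)))[, , 1],
                  error = function(e) NULL)
    if (!is.null(W)) {
      O <- tryCatch(chol2inv(chol(W)), error = function(e) NULL)
      if (!is.null(O)) return((O + t(O)) / 2)
    }
  }
  stop("inverse-Wishart draw failed after jittered retries")
}

#' Reshape between wide and long longitudinal formats
#'
#' `wide_to_long` stacks the occasion columns of a wide matrix into rows
#' with columns `id`, `occasion`, `time`, `y`; `long_to_wide` inverts it.
#' The round trip is lossless, including missing markers.
#'
#' @param wide Numeric `n` by `T` matrix (may contain `NA`).
#' @param time_codes Time codes attached to the occasions.
#' @param ids Row identifiers; default `1:n`.
#' @return `wide_to_long`: a data frame with `n * T` rows in (id, occasion)
#'   order. `long_to_wide`: a numeric matrix.
#' @export
wide_to_long <- function(wide, time_codes, ids = NULL) {
  Y <- as_outcome_matrix(wide)
  n <- nrow(Y)
  T_occ <- ncol(Y)
  if (length(time_codes) != T_occ)
    stop("`time_codes` length must equal the number of columns")
  if (is.null(ids)) ids <- seq_len(n)
  data.frame(id = rep(ids, each = T_occ),
             occasion = rep(seq_len(T_occ), times = n),
             time = rep(time_codes, times = n),
             y = as.vector(t(Y)))
}

#' @param long Data frame with columns `id`, `occasion`, `y` (as produced by
#'   `wide_to_long`); `(id, occasion)` pairs must be unique.
#' @rdname wide_to_long
#' @export
long_to_wide <- function(long) {
  stopifnot(all(c("id", "occasion", "y") %in% names(long)))
  if (anyDuplicated(long[c("id", "occasion")]))
    stop("duplicate (id, occasion) pairs")
  ids <- unique(long$id)
  occ <- sort(unique(long$occasion))
  Y <- matrix(NA_real_, length(ids), length(occ),
              dimnames = list(NULL, paste0("y", occ)))
  i <- match(long$id, ids)
  j <- match(long$occasion, occ)
  Y[cbind(i, j)] <- long$y
  Y
}
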