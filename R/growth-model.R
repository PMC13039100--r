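#' Specify a latent growth curve model
#'
#' A `growth_spec` describes the structural part of a linear or quadratic
#' latent growth curve model (LGCM): the polynomial order, the time codes
#' attached to the measurement occasions, and any latent covariances that the
#' analysis model constrains to zero. Residual variances are always freed per
#' occasion.
#'
#' @param order Polynomial order of the growth trajectory: 1 (linear,
#'   intercept + slope) or 2 (quadratic, intercept + linear + quadratic slope).
#' @param time_codes Numeric vector of time codes \eqn{t_j}, one per
#'   measurement occasion. Must contain at least `order + 2` occasions so the
#'   model is identified, and the codes must not all be equal.
#' @param fixed_zero_covariances Latent covariances constrained to zero in the
#'   analysis model, given as a list of factor-index pairs (1 = intercept,
#'   2 = linear slope, 3 = quadratic slope), e.g. `list(c(1, 3))` fixes the
#'   intercept--quadratic covariance at zero. Character labels
#'   (`"intercept"`, `"linear"`, `"quadratic"`) are also accepted.
#' @param residual_structure Only `"free-per-occasion"` is supported: one free
#'   residual variance per measurement occasion.
#'
#' @return An object of class `growth_spec` with elements `order`,
#'   `time_codes`, `n_occasions`, `n_factors`, `fixed_zero` (a two-column
#'   integer matrix, possibly with zero rows) and `residual_structure`.
#' @examples
#' growth_spec(1, 0:6)
#' growth_spec(2, 0:6, fixed_zero_covariances = list(c(1, 3)))
#' @export
growth_spec <- function(order, time_codes,
                        fixed_zero_covariances = list(),
                        residual_structure = "free-per-occasion") {
  if (!is.numeric(order) || length(order) != 1L || !(order %in% c(1, 2)))
    stop("`order` must be 1 (linear) or 2 (quadratic)")
  time_codes <- as.numeric(time_codes)
  if (any(!is.finite(time_codes)))
    stop("`time_codes` must be finite")
  T_occ <- length(time_codes)
  if (T_occ < order + 2)
    stop("need at least order + 2 = ", order + 2, " occasions, got ", T_occ)
  if (length(unique(time_codes)) == 1L)
    stop("`time_codes` must not be all equal")
  residual_structure <- match.arg(residual_structure, "free-per-occasion")
  q <- order + 1L

  fz <- normalize_factor_pairs(fixed_zero_covariances, q)
  structure(
    list(order = as.integer(order),
         time_codes = time_codes,
         n_occasions = T_occ,
         n_factors = q,
         fixed_zero = fz,
         residual_structure = residual_structure),
    class = "growth_spec")
}

factor_labels <- function(q) c("intercept", "linear", "quadratic")[seq_len(q)]

normalize_factor_pairs <- function(pairs, q) {
  labs <- factor_labels(q)
  out <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("row", "col")))
  for (p in pairs) {
    if (is.character(p)) p <- match(p, labs)
    p <- as.integer(p)
    if (length(p) != 2L || any(is.na(p)) || any(p < 1L) || any(p > q) ||
        p[1] == p[2])
      stop("invalid fixed-zero covariance pair")
    out <- rbind(out, sort(p))
  }
  unique(out)
}

#' @export
print.growth_spec <- function(x, ...) {
  cat(sprintf("Latent growth spec: order %d (%s), %d occasions\n",
              x$order, c("linear", "quadratic")[x$order], x$n_occasions))
  cat("  time codes:", paste(x$time_codes, collapse = ", "), "\n")
  if (nrow(x$fixed_zero)) {
    labs <- factor_labels(x$n_factors)
    cat("  fixed-zero covariances:",
        paste(apply(x$fixed_zero, 1L,
                    function(p) paste(labs[p], collapse = "-")),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Population parameter values for a latent growth model
#'
#' Bundles factor means, the factor covariance matrix \eqn{\Psi} and the
#' occasion-specific residual variances \eqn{\theta_j} of an LGCM.
#'
#' @param means Numeric vector of latent factor means (length
#'   `order + 1`): intercept, linear slope, and, for quadratic models,
#'   quadratic slope.
#' @param cov Symmetric positive-(semi)definite factor covariance matrix of
#'   the same dimension.
#' @param residual_vars Positive numeric vector of residual variances, one
#'   per occasion; a scalar is recycled.
#' @param n_occasions Number of occasions used to recycle a scalar
#'   `residual_vars`; ignored when `residual_vars` already has full length.
#'
#' @return Object of class `growth_params`.
#' @examples
#' growth_params(c(39.457, 8.063),
#'               matrix(c(28.776, 1.56, 1.56, 8.201), 2),
#'               residual_vars = 10, n_occasions = 7)
#' @export
growth_params <- function(means, cov, residual_vars, n_occasions = NULL) {
  means <- as.numeric(means)
  cov <- as.matrix(cov)
  q <- length(means)
  if (!all(dim(cov) == q)) stop("`cov` must be ", q, "x", q)
  if (max(abs(cov - t(cov))) > 1e-8) stop("`cov` must be symmetric")
  if (!is.null(n_occasions) && length(residual_vars) == 1L)
    residual_vars <- rep(residual_vars, n_occasions)
  residual_vars <- as.numeric(residual_vars)
  if (any(residual_vars <= 0)) stop("residual variances must be positive")
  structure(list(means = means, cov = (cov + t(cov)) / 2,
                 residual_vars = residual_vars),
            class = "growth_params")
}

#' Population models used in the simulation studies
#'
#' Returns the population growth model for one of the three simulation
#' studies: Study 1 is a linear model over seven occasions; Studies 2 and 3
#' share a quadratic population model over seven occasions (Study 3 differs
#' only in its misspecified *analysis* model, see [analysis_spec()]).
#' Occasions are coded \eqn{t_j = 0, \ldots, 6} by default.
#'
#' The population residual variances are not part of the published parameter
#' table; the defaults (10 on the Study 1 scale, 0.5 on the Study 2/3 scale)
#' are package assumptions, exposed through `residual_var`.
#'
#' @param study Study number, 1, 2 or 3.
#' @param residual_var Common residual variance across occasions; default 10
#'   for Study 1 and 0.5 for Studies 2--3.
#' @param time_codes Time codes; default `0:6`.
#'
#' @return A list with components `spec` (a [growth_spec()]) and `params`
#'   (a [growth_params()]).
#' @export
study_population <- function(study, residual_var = NULL, time_codes = 0:6) {
  study <- as.integer(study)
  if (!(study %in% 1:3)) stop("`study` must be 1, 2 or 3")
  if (study == 1) {
    if (is.null(residual_var)) residual_var <- 10
    spec <- growth_spec(1, time_codes)
    params <- growth_params(
      means = c(39.457, 8.063),
      cov = matrix(c(28.776, 1.56,
                     1.56, 8.201), 2, 2),
      residual_vars = residual_var, n_occasions = spec$n_occasions)
  } else {
    if (is.null(residual_var)) residual_var <- 0.5
    spec <- growth_spec(2, time_codes)
    params <- growth_params(
      means = c(1, 0.3, 0.5),
      cov = matrix(c(3.0, 0.3, 0.3,
                     0.3, 0.3, 0.0,
                     0.3, 0.0, 0.3), 3, 3),
      residual_vars = residual_var, n_occasions = spec$n_occasions)
  }
  list(spec = spec, params = params)
}

#' Analysis-model specification for a study
#'
#' Studies 1 and 2 analyze data with the correctly specified population
#' model. Study 3 uses the quadratic model with the intercept--quadratic
#' covariance incorrectly fixed at zero.
#'
#' @inheritParams study_population
#' @return A [growth_spec()].
#' @export
analysis_spec <- function(study, time_codes = 0:6) {
  study <- as.integer(study)
  if (study == 1) growth_spec(1, time_codes)
  else if (study == 2) growth_spec(2, time_codes)
  else if (study == 3)
    growth_spec(2, time_codes, fixed_zero_covariances = list(c(1, 3)))
  else stop("`study` must be 1, 2 or 3")
}

#' Factor loading matrix of a growth model
#'
#' Builds the \eqn{T \times (order+1)} loading matrix whose \eqn{j}-th row is
#' \eqn{(1, t_j, t_j^2, \ldots)}: a column of ones for the intercept and
#' powers of the time codes for the slope factors.
#'
#' @param spec A [growth_spec()].
#' @return Numeric matrix with `n_occasions` rows and `n_factors` columns.
#' @examples
#' loading_matrix(growth_spec(2, c(-1.5, -0.5, 0.5, 1, 2)))
#' @export
loading_matrix <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  L <- outer(spec$time_codes, 0:spec$order, `^`)
  colnames(L) <- factor_labels(spec$n_factors)
  L
}

#' Implied mean vector and covariance matrix
#'
#' Computes the moments of the repeated measures implied by an LGCM:
#' \eqn{\mu = \Lambda \alpha} and
#' \eqn{\Sigma = \Lambda \Psi \Lambda^\top + \Theta}, with \eqn{\Theta}
#' diagonal in the occasion residual variances.
#'
#' @param params A [growth_params()].
#' @param spec A [growth_spec()] whose dimensions agree with `params`.
#' @return A list of class `moment_structure` with elements `mean` (length
#'   \eqn{T}) and `cov` (\eqn{T \times T}, symmetric).
#' @export
implied_moments <- function(params, spec) {
  stopifnot(inherits(params, "growth_params"), inherits(spec, "growth_spec"))
  if (length(params$means) != spec$n_factors)
    stop("factor dimension mismatch between `params` and `spec`")
  if (length(params$residual_vars) != spec$n_occasions)
    stop("residual-variance length must equal the number of occasions")
  L <- loading_matrix(spec)
  mu <- drop(L %*% params$means)
  S <- L %*% params$cov %*% t(L) + diag(params$residual_vars,
                                        spec$n_occasions)
  structure(list(mean = mu, cov = (S + t(S)) / 2),
            class = "moment_structure")
}

#' Degrees of freedom of the growth-vs-saturated likelihood-ratio test
#'
#' The difference in free parameters between the saturated
#' multivariate-normal model (\eqn{T} means plus \eqn{T(T+1)/2} covariance
#' elements) and the hypothesized growth model (\eqn{q} factor means, the
#' free elements of \eqn{\Psi}, and \eqn{T} residual variances).
#'
#' @param spec A [growth_spec()].
#' @return Integer degrees of freedom.
#' @examples
#' lrt_df(growth_spec(2, c(-1.5, -0.5, 0.5, 1, 2)))  # 6
#' @export
lrt_df <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  T_occ <- spec$n_occasions
  q <- spec$n_factors
  saturated <- T_occ + T_occ * (T_occ + 1) / 2
  growth <- q + q * (q + 1) / 2 - nrow(spec$fixed_zero) + T_occ
  as.integer(saturated - growth)
}

n_free_growth_params <- function(spec) {
  q <- spec$n_factors
  as.integer(q + q * (q + 1) / 2 - nrow(spec$fixed_zero) + spec$n_occasions)
}

#' Names of the parameters of a growth model
#'
#' Canonical parameter naming used throughout fitting, pooling and
#' evaluation: factor means (`mean_*`), factor variances (`var_*`), free
#' factor covariances (`cov_*_*`), and per-occasion residual variances
#' (`resvar_j`).
#'
#' @param spec A [growth_spec()].
#' @param growth_only If `TRUE`, drop the residual-variance names and return
#'   only the latent growth parameters.
#' @return Character vector of parameter names.
#' @export
param_names <- function(spec, growth_only = FALSE) {
  labs <- factor_labels(spec$n_factors)
  nm <- c(paste0("mean_", labs), paste0("var_", labs))
  q <- spec$n_factors
  for (a in seq_len(q - 1)) for (b in seq(a + 1, q)) {
    if (!pair_is_fixed(spec, a, b))
      nm <- c(nm, paste0("cov_", labs[a], "_", labs[b]))
  }
  if (!growth_only)
    nm <- c(nm, paste0("resvar_", seq_len(spec$n_occasions)))
  nm
}

pair_is_fixed <- function(spec, a, b) {
  fz <- spec$fixed_zero
  nrow(fz) > 0 && any(fz[, 1] == min(a, b) & fz[, 2] == max(a, b))
}

#' True parameter values in the canonical naming
#'
#' Flattens a [growth_params()] object into the named vector layout of
#' [param_names()], for use as the truth in bias/coverage computations.
#'
#' @inheritParams implied_moments
#' @param growth_only Drop residual variances (default `TRUE`).
#' @return Named numeric vector.
#' @export
true_param_vector <- function(params, spec, growth_only = TRUE) {
  labs <- factor_labels(spec$n_factors)
  q <- spec$n_factors
  out <- c(stats::setNames(params$means, paste0("mean_", labs)),
           stats::setNames(diag(params$cov), paste0("var_", labs)))
  for (a in seq_len(q - 1)) for (b in seq(a + 1, q)) {
    if (!pair_is_fixed(spec, a, b))
      out[paste0("cov_", labs[a], "_", labs[b])] <- params$cov[a, b]
  }
  if (!growth_only)
    out <- c(out, stats::setNames(params$residual_vars,
                                  paste0("resvar_",
                                         seq_len(spec$n_occasions))))
  out
}
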