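#' Occasion-wise missing-data proportion schedules
#'
#' The two expected missing-proportion schedules used in the simulation
#' studies: `"small"` rises to 30% missing at the last of seven occasions,
#' `"large"` to 60%. The first occasion is always completely observed.
#'
#' @param name `"small"` or `"large"`, or a numeric vector of per-occasion
#'   proportions (first element must be 0) passed through unchanged.
#' @return Numeric vector of length 7 (or the input length).
#' @export
missing_schedule <- function(name) {
  if (is.numeric(name)) {
    if (name[1] != 0) stop("first occasion must be fully observed")
    if (any(name < 0 | name >= 1)) stop("proportions must lie in [0, 1)")
    return(as.numeric(name))
  }
  switch(match.arg(name, c("small", "large")),
         small = c(0, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
         large = c(0, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60))
}

#' Specify a missingness mechanism
#'
#' Describes occasion-wise missingness driven by the logistic model
#' \eqn{p_{ij} = \mathrm{logit}^{-1}(b_{0j} + b_1 Y_{i,j-1})}: under MCAR
#' \eqn{b_1 = 0}; under MAR \eqn{b_1 = 0.4}, so the probability of a value
#' going missing increases with the previous occasion's (pre-deletion)
#' outcome, emulating outcome-dependent attrition. The per-occasion
#' intercepts \eqn{b_{0j}} are calibrated afterwards with
#' [calibrate_missingness()] so the expected missing proportions match a
#' target schedule.
#'
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param proportions Schedule name or numeric vector, see
#'   [missing_schedule()].
#' @param b1 Slope on the previous occasion's outcome; defaults to 0 for
#'   MCAR and 0.4 for MAR. MCAR requires `b1 = 0`.
#' @param standardize If `TRUE` (the default), the previous outcome is
#'   standardized (population marginal mean/SD) before entering the
#'   logistic predictor, so a given slope induces the same selection
#'   severity regardless of the outcome's scale. With `FALSE` the slope
#'   applies to the raw outcome; on outcomes far from unit scale the
#'   selection becomes near-deterministic and, because deletion conditions
#'   on pre-deletion values, effectively not-at-random.
#' @return Object of class `missingness_spec` (uncalibrated until
#'   [calibrate_missingness()] is applied).
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR"),
                             proportions = "small", b1 = NULL,
                             standardize = TRUE) {
  mechanism <- match.arg(mechanism)
  if (is.null(b1)) b1 <- if (mechanism == "MAR") 0.4 else 0
  if (mechanism == "MCAR" && b1 != 0)
    stop("MCAR requires b1 = 0")
  if (mechanism == "MAR" && b1 == 0)
    stop("MAR requires a nonzero b1")
  structure(list(mechanism = mechanism,
                 target_proportions = missing_schedule(proportions),
                 b1 = b1, standardize = standardize,
                 calibrated_intercepts = NULL),
            class = "missingness_spec")
}

#' Calibrate the logistic missingness intercept for one occasion
#'
#' Solves \eqn{E[\mathrm{logit}^{-1}(b_0 + b_1 Y)] = } `target` for
#' \eqn{b_0}, with \eqn{Y} normal with the supplied marginal mean and
#' variance, by numerical integration and root bracketing to an absolute
#' error below `tol`. With `b1 = 0` the closed-form logit inverse is used.
#'
#' @param target Expected missing proportion, in `[0, 1)`. A target of 0
#'   returns `-Inf` (the "never missing" sentinel).
#' @param b1 Logistic slope on `Y`.
#' @param marginal_mean,marginal_var Marginal moments of the predictor
#'   occasion under the population model.
#' @param tol Absolute calibration tolerance (default `1e-6`).
#' @return The calibrated intercept \eqn{b_0}.
#' @examples
#' calibrate_b0(0.25, 0, 0, 1)  # log(1/3)
#' @export
calibrate_b0 <- function(target, b1, marginal_mean, marginal_var,
                         tol = 1e-6) {
  if (target < 0 || target >= 1) stop("`target` must lie in [0, 1)")
  if (marginal_var <= 0) stop("`marginal_var` must be positive")
  if (target == 0) return(-Inf)
  if (b1 == 0) return(stats::qlogis(target))
  sdv <- sqrt(marginal_var)
  expected <- function(b0) {
    stats::integrate(function(z)
      stats::plogis(b0 + b1 * (marginal_mean + sdv * z)) * stats::dnorm(z),
      lower = -10, upper = 10, rel.tol = 1e-10)$value
  }
  center <- stats::qlogis(target) - b1 * marginal_mean
  half <- 50 * (abs(b1) * sdv + 1)
  stats::uniroot(function(b0) expected(b0) - target,
                 lower = center - half, upper = center + half,
                 tol = tol, extendInt = "yes")$root
}

#' Calibrate a missingness specification against a population model
#'
#' Fills the per-occasion intercepts of a [missingness_spec()] so that the
#' expected missing proportion at each occasion matches the target schedule,
#' using the *population* marginal distribution of the previous occasion's
#' outcome (not any particular sample).
#'
#' @param mspec A [missingness_spec()].
#' @param params,spec Population model, see [growth_params()] and
#'   [growth_spec()].
#' @return The calibrated `missingness_spec`.
#' @export
calibrate_missingness <- function(mspec, params, spec) {
  stopifnot(inherits(mspec, "missingness_spec"))
  mom <- implied_moments(params, spec)
  T_occ <- spec$n_occasions
  tp <- mspec$target_proportions
  if (length(tp) != T_occ)
    stop("schedule length must equal the number of occasions")
  b0 <- rep(-Inf, T_occ)
  scale_mean <- rep(0, T_occ)
  scale_sd <- rep(1, T_occ)
  for (j in seq(2, T_occ)) {
    mu_prev <- mom$mean[j - 1]
    v_prev <- mom$cov[j - 1, j - 1]
    if (mspec$standardize) {
      scale_mean[j] <- mu_prev
      scale_sd[j] <- sqrt(v_prev)
      b0[j] <- calibrate_b0(tp[j], mspec$b1, 0, 1)
    } else {
      b0[j] <- calibrate_b0(tp[j], mspec$b1, mu_prev, v_prev)
    }
  }
  mspec$calibrated_intercepts <- b0
  mspec$predictor_center <- scale_mean
  mspec$predictor_scale <- scale_sd
  mspec
}

#' Simulate complete repeated-measures data from a growth model
#'
#' Draws `n` i.i.d. rows from the multivariate normal distribution implied
#' by the population growth model.
#'
#' @param n Number of individuals.
#' @param params,spec Population model.
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return Numeric `n` by `T` matrix with columns `y1..yT`.
#' @export
simulate_growth <- function(n, params, spec, seed = NULL) {
  if (n < 1) stop("`n` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  mom <- implied_moments(params, spec)
  T_occ <- spec$n_occasions
  R <- chol(mom$cov)
  Y <- matrix(stats::rnorm(n * T_occ), n, T_occ) %*% R
  Y <- sweep(Y, 2L, mom$mean, `+`)
  colnames(Y) <- paste0("y", seq_len(T_occ))
  Y
}

#' Impose occasion-wise missingness on complete data
#'
#' For each occasion \eqn{j \ge 2} independently, deletes entry \eqn{(i, j)}
#' with probability \eqn{\mathrm{logit}^{-1}(b_{0j} + b_1 Y_{i,j-1})}, where
#' \eqn{Y_{i,j-1}} is the complete pre-deletion value. The first occasion is
#' never deleted; deletion is independent across occasions (non-monotone
#' missingness).
#'
#' @param data Complete numeric matrix from [simulate_growth()].
#' @param mspec A calibrated [missingness_spec()].
#' @param seed Optional integer seed.
#' @return Object of class `incomplete_data`: a list with `values` (the
#'   matrix with `NA` markers), `complete_shadow` (the pre-deletion matrix,
#'   kept for diagnostics) and `mask` (logical matrix of deleted cells).
#' @export
impose_missingness <- function(data, mspec, seed = NULL) {
  stopifnot(inherits(mspec, "missingness_spec"))
  if (is.null(mspec$calibrated_intercepts))
    stop("`mspec` is uncalibrated; run calibrate_missingness() first")
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(data)
  T_occ <- ncol(Y)
  if (length(mspec$calibrated_intercepts) != T_occ)
    stop("`mspec` was calibrated for a different number of occasions")
  n <- nrow(Y)
  mask <- matrix(FALSE, n, T_occ)
  for (j in seq(2, T_occ)) {
    b0 <- mspec$calibrated_intercepts[j]
    if (!is.finite(b0)) next
    pred <- (Y[, j - 1] - mspec$predictor_center[j]) /
      mspec$predictor_scale[j]
    p <- stats::plogis(b0 + mspec$b1 * pred)
    mask[, j] <- stats::runif(n) < p
  }
  values <- Y
  values[mask] <- NA_real_
  structure(list(values = values, complete_shadow = Y, mask = mask,
                 ids = seq_len(n), mechanism = mspec$mechanism),
            class = "incomplete_data")
}

#' Write/read wide-format data with an empty-field missing marker
#'
#' Plain CSV serialization of a wide repeated-measures table; missing cells
#' are written as empty fields.
#'
#' @param data Matrix or data frame of outcomes.
#' @param path File path.
#' @return `read_wide_csv` returns a numeric matrix.
#' @export
write_wide_csv <- function(data, path) {
  utils::write.csv(as.data.frame(as.matrix(data)), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_wide_csv
#' @export
read_wide_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  as.matrix(df)
}
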