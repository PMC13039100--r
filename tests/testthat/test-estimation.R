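test_that("pattern likelihood matches a brute-force per-row oracle", {
  set.seed(21)
  mu <- c(1, -0.5, 2, 0.3)
  A <- matrix(rnorm(16), 4)
  Sigma <- crossprod(A) + diag(0.5, 4)
  Y <- matrix(rnorm(80), 20, 4) %*% chol(Sigma)
  Y <- sweep(Y, 2, mu, `+`)
  Ymiss <- Y
  Ymiss[cbind(sample(20, 12, TRUE), sample(2:4, 12, TRUE))] <- NA
  expect_equal(pattern_loglik(Ymiss, mu, Sigma),
               rowwise_loglik(Ymiss, mu, Sigma))
  # complete data reduce to the standard MVN log-likelihood
  expect_equal(pattern_loglik(Y, mu, Sigma), rowwise_loglik(Y, mu, Sigma))
  # one row observed only at occasion 1: univariate normal density
  y1 <- matrix(c(1.7, NA, NA, NA), 1)
  expect_equal(pattern_loglik(y1, mu, Sigma),
               dnorm(1.7, mu[1], sqrt(Sigma[1, 1]), log = TRUE))
})

test_that("FIML recovers population parameters from complete data", {
  pop <- study_population(1)
  Y <- simulate_growth(20000, pop$params, pop$spec, seed = 22)
  fit <- fit_growth(Y, pop$spec, se = FALSE)
  expect_true(fit$converged)
  truth <- true_param_vector(pop$params, pop$spec, growth_only = TRUE)
  # Monte-Carlo tolerance at n = 20000
  expect_equal(unname(fit$estimates["mean_linear"]), 8.063,
               tolerance = 0.02)
  expect_equal(fit$estimates[names(truth)], truth, tolerance = 0.1)
  expect_equal(unname(fit$estimates[paste0("resvar_", 1:7)]), rep(10, 7),
               tolerance = 0.1)
})

test_that("a fixed-zero covariance removes one free parameter", {
  pop <- toy_linear_pop()
  spec2 <- growth_spec(2, 0:4)
  spec3 <- growth_spec(2, 0:4, fixed_zero_covariances = list(c(1, 3)))
  expect_identical(n_free_growth_params(spec2) - n_free_growth_params(spec3),
                   1L)
  p2 <- study_population(2)
  Y <- simulate_growth(400, p2$params, p2$spec, seed = 23)
  f3 <- fit_growth(Y, analysis_spec(3), se = FALSE)
  expect_true(f3$converged)
  expect_false("cov_intercept_quadratic" %in% names(f3$estimates))
  expect_identical(length(f3$estimates) + 1L,
                   length(fit_growth(Y, analysis_spec(2),
                                     se = FALSE)$estimates))
})

test_that("saturated fit is closed-form on complete data and EM otherwise", {
  pop <- toy_linear_pop()
  Y <- simulate_growth(200, pop$params, pop$spec, seed = 24)
  sat <- fit_saturated(Y)
  expect_equal(sat$mean, colMeans(Y))
  expect_equal(sat$cov, cov(Y) * (199 / 200))
  expect_identical(sat$iterations, 0L)

  set.seed(25)
  Ym <- mask_mcar(Y, 0.25)
  sat_m <- fit_saturated(Ym)
  expect_true(sat_m$converged)
  # EM solution maximizes the observed-data likelihood: compare with a
  # direct numerical optimization over all moment parameters
  T_occ <- 3
  Ysmall <- Ym[1:30, 1:3]
  st_obj <- function(par) {
    mu <- par[1:3]
    L <- matrix(0, 3, 3)
    L[lower.tri(L, diag = TRUE)] <- par[4:9]
    diag(L) <- exp(diag(L))
    S <- tcrossprod(L)
    -pattern_loglik(Ysmall, mu, S)
  }
  sat_s <- fit_saturated(Ysmall, tol = 1e-10)
  L0 <- t(chol(sat_s$cov))
  diag(L0) <- log(diag(L0))
  par0 <- c(sat_s$mean, L0[lower.tri(L0, diag = TRUE)])
  opt <- optim(par0 + 0.05, st_obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  expect_equal(-opt$value, sat_s$loglik, tolerance = 1e-4)
})

test_that("likelihood ratio test behaves at its boundaries", {
  pop <- toy_linear_pop()
  Y <- simulate_growth(300, pop$params, pop$spec, seed = 26)
  sat <- fit_saturated(Y)
  # saturated against itself: statistic 0, p = 1
  self <- likelihood_ratio_test(
    structure(list(loglik = sat$loglik, converged = TRUE, n_used = 300,
                   spec = pop$spec), class = "growth_fit"),
    sat, df = lrt_df(pop$spec))
  expect_identical(self$statistic, 0)
  expect_identical(self$p_value, 1)

  fit <- fit_growth(Y, pop$spec, se = FALSE,
                    start = list(mean = sat$mean, cov = sat$cov))
  lr <- likelihood_ratio_test(fit, sat)
  expect_gte(lr$statistic, 0)
  expect_identical(lr$df, lrt_df(pop$spec))
})

test_that("LRT statistic is chi-square distributed under the correct model", {
  pop <- toy_linear_pop()
  k <- lrt_df(pop$spec)
  set.seed(27)
  stats <- replicate(500, {
    Y <- simulate_growth(600, pop$params, pop$spec)
    sat <- fit_saturated(Y)
    fit <- fit_growth(Y, pop$spec, se = FALSE,
                      start = list(mean = sat$mean, cov = sat$cov))
    likelihood_ratio_test(fit, sat)$statistic
  })
  expect_equal(mean(stats), k, tolerance = 0.1)  # chi-square mean property
  expect_gt(ks.test(stats, pchisq, df = k)$p.value, 0.01)
})

test_that("LRT is invariant to row order", {
  pop <- toy_linear_pop()
  set.seed(28)
  Y <- mask_mcar(simulate_growth(250, pop$params, pop$spec), 0.2)
  stat_of <- function(Z) {
    sat <- fit_saturated(Z)
    fit <- fit_growth(Z, pop$spec, se = FALSE,
                      start = list(mean = sat$mean, cov = sat$cov))
    likelihood_ratio_test(fit, sat)$statistic
  }
  expect_equal(stat_of(Y), stat_of(Y[sample(nrow(Y)), ]), tolerance = 1e-5)
})

test_that("FIML under MCAR matches complete-data precision expectations", {
  pop <- toy_linear_pop()
  reps <- 100
  set.seed(29)
  est <- t(replicate(reps, {
    Y <- mask_mcar(simulate_growth(600, pop$params, pop$spec), 0.2)
    sat <- fit_saturated(Y)
    fit_growth(Y, pop$spec, se = FALSE,
               start = list(mean = sat$mean, cov = sat$cov))$estimates
  }))
  truth <- true_param_vector(pop$params, pop$spec)
  for (p in c("mean_intercept", "mean_linear")) {
    mc_se <- sd(est[, p]) / sqrt(reps)
    expect_lt(abs(mean(est[, p]) - truth[[p]]), 3 * mc_se)
  }
})

test_that("standard errors and Wald intervals are coherent", {
  pop <- toy_linear_pop()
  Y <- simulate_growth(800, pop$params, pop$spec, seed = 30)
  fit <- fit_growth(Y, pop$spec, se = TRUE)
  expect_true(fit$information_ok)
  expect_true(all(fit$se > 0))
  ci95 <- wald_intervals(fit, 0.95)
  ci90 <- wald_intervals(fit, 0.90)
  expect_true(all(ci90$lower > ci95$lower & ci90$upper < ci95$upper))
  # quantile arithmetic: estimate 1, SE 0.5 at 95%
  row <- ci95[1, ]
  z <- qnorm(0.975)
  expect_equal(row$lower, row$estimate - z * row$se)
  fake <- fit
  fake$estimates <- c(theta = 1)
  fake$se <- c(theta = 0.5)
  ci <- wald_intervals(fake)
  expect_equal(round(c(ci$lower, ci$upper), 3), c(0.020, 1.980))
})

test_that("rows with nothing observed are dropped with a warning", {
  pop <- toy_linear_pop()
  Y <- simulate_growth(50, pop$params, pop$spec, seed = 31)
  Y[3, ] <- NA
  expect_warning(st <- pattern_stats(Y), "dropped")
  expect_identical(attr(st, "n_used"), 49L)
})

test_that("the analytic likelihood gradient matches finite differences", {
  spec <- analysis_spec(3)            # quadratic with a fixed-zero covariance
  pop <- study_population(3)
  Y <- simulate_growth(120, pop$params, pop$spec, seed = 32)
  set.seed(33)
  Y[sample(length(Y), 100)] <- NA
  st <- pattern_stats(Y)
  map <- growth_parmap(spec)
  Lam <- loading_matrix(spec)
  em <- em_mvn(Y)
  # perturb off the optimum so the gradient is far from zero
  par0 <- growth_start_values(em$mean, em$cov, spec, map) * 1.07 + 0.03
  negll <- function(par) {
    p <- unpack_growth_par(par, map)
    -loglik_from_stats(st, drop(Lam %*% p$alpha),
                       Lam %*% p$Psi %*% t(Lam) + diag(p$theta, map$T_occ))
  }
  p <- unpack_growth_par(par0, map)
  g <- loglik_grad_from_stats(st, drop(Lam %*% p$alpha),
                              Lam %*% p$Psi %*% t(Lam) +
                                diag(p$theta, map$T_occ))
  Gpsi <- t(Lam) %*% g$GSigma %*% Lam
  ana <- unname(c(-drop(crossprod(Lam, g$gmu)),
                  -(2 * (Gpsi %*% p$L))[map$Lidx],
                  -diag(g$GSigma) * p$theta))
  num <- pracma::grad(negll, par0)
  expect_equal(ana, num, tolerance = 1e-6)
})
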