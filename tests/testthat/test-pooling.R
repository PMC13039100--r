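test_that("Rubin's rules reproduce the hand-computed combination", {
  # m = 2, estimates {1, 3}, variances {1, 1}
  pooled <- pool_rubin(matrix(c(1, 3), 2, 1,
                              dimnames = list(NULL, "theta")),
                       matrix(c(1, 1), 2, 1,
                              dimnames = list(NULL, "theta")))
  expect_equal(unname(pooled$estimates), 2)
  expect_equal(unname(pooled$between_var), 2)
  expect_equal(unname(pooled$within_var), 1)
  expect_equal(unname(pooled$total_var), 4)
  # identity V_pooled = V_W + (1 + 1/m) V_B
  expect_equal(pooled$total_var,
               pooled$within_var + (1 + 1 / 2) * pooled$between_var)
})

test_that("Rubin pooling degenerates correctly and obeys its limit", {
  est <- matrix(5, 10, 1, dimnames = list(NULL, "a"))
  var <- matrix(0.3, 10, 1, dimnames = list(NULL, "a"))
  pooled <- pool_rubin(est, var)
  expect_equal(unname(pooled$between_var), 0)
  expect_equal(unname(pooled$total_var), 0.3)
  # V_pooled -> V_W + V_B as m grows with V_B held fixed
  set.seed(51)
  base <- rnorm(20)
  for (m in c(10, 200)) {
    estm <- matrix(rep(base, length.out = m) - mean(base) + 1, m, 1,
                   dimnames = list(NULL, "a"))
    p <- pool_rubin(estm, matrix(1, m, 1, dimnames = list(NULL, "a")))
    expect_equal(unname(p$total_var),
                 unname(1 + p$between_var * (1 + 1 / m)))
  }
  expect_error(pool_rubin(est[1, , drop = FALSE], var[1, , drop = FALSE]),
               "at least 2")
})

test_that("D2 matches a step-by-step hand oracle", {
  Ti <- c(10, 12, 14)
  k <- 2
  m <- 3
  # independent hand computation of the printed formula
  r2 <- (1 + 1 / m) * var(sqrt(Ti))
  expected <- (mean(Ti) / k - (m + 1) / (m - 1) * r2) / (1 + r2)
  nu2 <- k^(-3 / m) * (m - 1) * (1 + 1 / r2)^2
  d2 <- pool_d2(Ti, k)
  expect_equal(d2$statistic, expected)
  expect_equal(d2$ariv, r2)
  expect_equal(d2$df2, nu2)
  expect_equal(d2$p_value, pf(expected, k, nu2, lower.tail = FALSE))
})

test_that("D2 degenerates to T/k with a chi-square reference", {
  d2 <- pool_d2(rep(9, 5), k = 3)
  expect_equal(d2$statistic, 3)
  expect_equal(d2$ariv, 0)
  expect_equal(d2$p_value, pchisq(9, 3, lower.tail = FALSE))
})

test_that("D2 decreases in the between-imputation spread at fixed mean", {
  k <- 4
  base <- c(10, 10, 10, 10)
  spreads <- c(0.5, 1.5, 3)
  vals <- sapply(spreads, function(s)
    pool_d2(base + c(-s, -s / 3, s / 3, s), k)$statistic)
  expect_true(all(diff(vals) < 0))
})

make_imputed_fits <- function(n = 200, frac = 0.2, m = 5, seed = 52) {
  pop <- toy_linear_pop()
  set.seed(seed)
  Y <- mask_mcar(simulate_growth(n, pop$params, pop$spec), frac)
  imp <- impute_emb(Y, m = m)
  sats <- lapply(imp$datasets, fit_saturated)
  fits <- lapply(seq_len(m), function(i)
    fit_growth(imp$datasets[[i]], pop$spec, se = FALSE,
               start = list(mean = sats[[i]]$mean, cov = sats[[i]]$cov)))
  list(pop = pop, imp = imp, fits = fits, sats = sats,
       k = lrt_df(pop$spec))
}

test_that("D3 and D4 collapse to T/k when all imputations are identical", {
  pop <- toy_linear_pop()
  Y <- simulate_growth(150, pop$params, pop$spec, seed = 53)
  imp <- impute_emb(Y, m = 4, seed = 1)      # complete data: m copies
  sats <- lapply(imp$datasets, fit_saturated)
  fits <- lapply(seq_len(4), function(i)
    fit_growth(imp$datasets[[i]], pop$spec, se = FALSE,
               start = list(mean = sats[[i]]$mean, cov = sats[[i]]$cov)))
  k <- lrt_df(pop$spec)
  T0 <- max(-2 * (fits[[1]]$loglik - sats[[1]]$loglik), 0)

  d3 <- pool_d3(imp, pop$spec, fits, sats)
  expect_equal(d3$ariv, 0, tolerance = 1e-4)
  expect_equal(d3$statistic, T0 / k, tolerance = 1e-3)

  d4 <- pool_d4(imp, pop$spec, fits, sats)
  # stacked data replicate each row m times: T_stacked = m * T
  expect_equal(d4$Tbar_stacked, T0, tolerance = 1e-3)
  expect_equal(d4$statistic, T0 / k, tolerance = 1e-3)
  expect_lt(abs(d4$ariv), 1e-3)
})

test_that("D3 and D4 agree on genuinely imputed data and D4 is nonnegative", {
  x <- make_imputed_fits()
  d3 <- pool_d3(x$imp, x$pop$spec, x$fits, x$sats)
  d4 <- pool_d4(x$imp, x$pop$spec, x$fits, x$sats)
  expect_gte(d4$statistic, 0)
  expect_true(is.finite(d3$statistic))
  expect_equal(d3$Tbar_LR, d4$Tbar_LR)
  # both pool the same evidence; under MCAR they should be close
  expect_equal(d3$statistic, d4$statistic, tolerance = 0.5)
  expect_true(d3$p_value >= 0 && d3$p_value <= 1)
  expect_true(d4$p_value >= 0 && d4$p_value <= 1)
})

test_that("pooled p-values are invariant to imputation order", {
  x <- make_imputed_fits(m = 6, seed = 54)
  perm <- c(4, 1, 6, 2, 5, 3)
  imp_p <- x$imp
  imp_p$datasets <- imp_p$datasets[perm]
  Ti <- mapply(function(f, s) max(-2 * (f$loglik - s$loglik), 0),
               x$fits, x$sats)
  expect_equal(pool_d2(Ti, x$k)$p_value, pool_d2(Ti[perm], x$k)$p_value)
  expect_equal(pool_d3(x$imp, x$pop$spec, x$fits, x$sats)$p_value,
               pool_d3(imp_p, x$pop$spec, x$fits[perm], x$sats[perm])$p_value,
               tolerance = 1e-8)
  expect_equal(pool_d4(x$imp, x$pop$spec, x$fits, x$sats)$p_value,
               pool_d4(imp_p, x$pop$spec, x$fits[perm], x$sats[perm])$p_value,
               tolerance = 1e-6)
})
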