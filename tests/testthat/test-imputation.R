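test_that("EM on complete data returns sample moments immediately", {
  pop <- toy_linear_pop()
  Y <- simulate_growth(120, pop$params, pop$spec, seed = 41)
  em <- em_mvn(Y)
  expect_equal(unname(em$mean), unname(colMeans(Y)))
  expect_equal(unname(em$cov), unname(cov(Y) * (119 / 120)), tolerance = 1e-10)
  expect_identical(em$iterations, 1L)
})

test_that("EM matches the closed-form monotone-missingness ML solution", {
  # bivariate monotone pattern: y1 complete, y2 missing for a block.
  # Closed-form ML (factorization): y1 moments from all rows, conditional
  # regression of y2 on y1 from the complete rows.
  set.seed(42)
  n <- 400
  y1 <- rnorm(n, 5, 2)
  y2 <- 1 + 0.7 * y1 + rnorm(n, 0, 1)
  y2[201:400] <- NA
  Y <- cbind(y1, y2)

  cc <- 1:200
  fit <- lm(y2[cc] ~ y1[cc])
  b <- coef(fit)
  s2e <- mean(resid(fit)^2)
  mu1 <- mean(y1)
  s11 <- mean((y1 - mu1)^2)
  mu2 <- b[1] + b[2] * mu1
  s12 <- b[2] * s11
  s22 <- s2e + b[2]^2 * s11

  em <- em_mvn(Y, tol = 1e-10)
  expect_equal(unname(em$mean), unname(c(mu1, mu2)), tolerance = 1e-6)
  expect_equal(unname(em$cov), unname(matrix(c(s11, s12, s12, s22), 2)),
               tolerance = 1e-5)
})

test_that("EM log-likelihood trace is non-decreasing", {
  pop <- toy_linear_pop()
  set.seed(43)
  Y <- mask_mcar(simulate_growth(150, pop$params, pop$spec), 0.3)
  em <- em_mvn(Y, tol = 1e-9)
  expect_true(all(diff(em$loglik_trace) > -1e-8))
  expect_true(em$converged)
})

test_that("all imputers preserve observed cells and vary imputed cells", {
  pop <- toy_linear_pop()
  set.seed(44)
  Y <- mask_mcar(simulate_growth(120, pop$params, pop$spec), 0.2)
  mask <- is.na(Y)
  imps <- list(
    impute_emb(Y, m = 4, seed = 1),
    impute_fcs(Y, m = 4, iterations = 60, burn_in = 20, seed = 1),
    impute_mlm(Y, time_codes = 0:4, form = "linear", m = 4,
               iterations = 60, burn_in = 20, seed = 1),
    impute_mlm(Y, time_codes = 0:4, form = "quadratic", m = 4,
               iterations = 60, burn_in = 20, seed = 1))
  for (imp in imps) {
    expect_identical(imp$m, 4L)
    for (d in imp$datasets) {
      expect_false(anyNA(d))
      expect_identical(d[!mask], Y[!mask])
    }
    # between-imputation variability in at least one imputed cell
    cells <- sapply(imp$datasets, function(d) d[mask])
    expect_gt(max(apply(cells, 1, var)), 0)
  }
})

test_that("imputers short-circuit on complete data", {
  pop <- toy_linear_pop()
  Y <- simulate_growth(40, pop$params, pop$spec, seed = 45)
  for (imp in list(impute_emb(Y, m = 3, seed = 1),
                   impute_fcs(Y, m = 3, iterations = 10, burn_in = 5,
                              seed = 1),
                   impute_mlm(Y, time_codes = 0:4, form = "linear", m = 3,
                              iterations = 10, burn_in = 5, seed = 1))) {
    expect_true(all(vapply(imp$datasets, identical, logical(1), Y)))
  }
})

test_that("imputation is seed-deterministic", {
  pop <- toy_linear_pop()
  set.seed(46)
  Y <- mask_mcar(simulate_growth(100, pop$params, pop$spec), 0.2)
  expect_identical(impute_emb(Y, m = 3, seed = 9)$datasets,
                   impute_emb(Y, m = 3, seed = 9)$datasets)
  expect_identical(
    impute_fcs(Y, m = 3, iterations = 40, burn_in = 10, seed = 9)$datasets,
    impute_fcs(Y, m = 3, iterations = 40, burn_in = 10, seed = 9)$datasets)
  expect_identical(
    impute_mlm(Y, 0:4, "linear", m = 3, iterations = 40, burn_in = 10,
               seed = 9)$datasets,
    impute_mlm(Y, 0:4, "linear", m = 3, iterations = 40, burn_in = 10,
               seed = 9)$datasets)
})

test_that("FCS imputations reproduce the true conditional distribution", {
  # MCAR bivariate toy: the imputed y2 | y1 distribution should match the
  # population conditional moments at long chain lengths
  set.seed(47)
  n <- 600
  y1 <- rnorm(n, 0, 1)
  y2 <- 2 + 1.5 * y1 + rnorm(n, 0, 0.8)
  Y <- cbind(y1 = y1, y2 = y2)
  miss <- sample(n, 200)
  Y[miss, 2] <- NA
  imp <- impute_fcs(Y, m = 25, iterations = 600, burn_in = 300, seed = 5)
  imputed <- sapply(imp$datasets, function(d) d[miss, 2])
  resid <- sweep(imputed, 1, 2 + 1.5 * y1[miss])
  expect_lt(abs(mean(resid)), 0.12)
  expect_equal(sd(as.vector(resid)), 0.8, tolerance = 0.12)
})

test_that("multilevel imputation model recovers the fixed growth effects", {
  pop <- study_population(1)
  set.seed(48)
  ms <- calibrate_missingness(missingness_spec("MCAR", "small"),
                              pop$params, pop$spec)
  inc <- impose_missingness(simulate_growth(600, pop$params, pop$spec), ms)
  imp <- impute_mlm(inc, time_codes = 0:6, form = "linear", m = 10,
                    iterations = 600, burn_in = 300, seed = 6)
  # column means of the completed data should track the population
  # trajectory (intercept 39.457, slope 8.063)
  trend <- colMeans(Reduce(`+`, imp$datasets) / imp$m)
  slope <- coef(lm(trend ~ I(0:6)))
  expect_equal(unname(slope[1]), 39.457, tolerance = 0.8)
  expect_equal(unname(slope[2]), 8.063, tolerance = 0.25)
})

test_that("wide/long reshaping is a lossless bijection", {
  Y <- matrix(c(1, 2, NA, 4, 5, 6), 3, 2)
  long <- wide_to_long(Y, time_codes = c(0, 1))
  expect_identical(nrow(long), 6L)
  expect_equal(unname(long_to_wide(long)), unname(Y))
  # permuted long rows reshape into the same canonical wide layout
  perm <- long[sample(nrow(long)), ]
  expect_equal(unname(long_to_wide(perm[order(perm$id, perm$occasion), ])),
               unname(Y))
  bad <- rbind(long, long[1, ])
  expect_error(long_to_wide(bad), "duplicate")
  pop <- toy_linear_pop()
  set.seed(49)
  Ym <- mask_mcar(simulate_growth(30, pop$params, pop$spec), 0.3)
  expect_equal(unname(long_to_wide(wide_to_long(Ym, 0:4))), unname(Ym))
})
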