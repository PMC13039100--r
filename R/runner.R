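ALL_METHODS <- c("FIML", "MI-wEMB", "MI-wFCS", "MI-llMLM", "MI-lqMLM")

#' Deterministic hierarchical seed derivation
#'
#' Folds a master seed and any number of labels (condition keys, replication
#' indices, method names) into a reproducible 31-bit seed, so any single
#' replication of a study can be re-run in isolation.
#'
#' @param master Integer master seed.
#' @param ... Labels (coerced to character) identifying the sub-stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- (abs(as.double(master)) + 1) %% 2147483647
  for (p in parts)
    for (ch in utf8ToInt(p))
      h <- (h * 69069 + ch) %% 2147483647
  as.integer(max(h, 1))
}

methods_for_study <- function(study) {
  if (study == 1) ALL_METHODS
  else c("FIML", "MI-wEMB", "MI-wFCS", "MI-lqMLM")
}

#' Run one simulation condition
#'
#' Executes the generate / delete / handle / evaluate cycle for a single
#' cell of the simulation design: draw complete data from the study's
#' population growth model, impose the calibrated MCAR/MAR missingness,
#' handle the missing data with one technique (FIML or one of the four MI
#' methods), and aggregate standardized bias, MSE, confidence-interval
#' coverage and LRT rejection rates across replications. For MI methods the
#' per-imputation growth and saturated fits are pooled with Rubin's rules
#' (estimates) and with the requested D2/D3/D4 strategies (test statistics).
#'
#' Replications in which any required fit fails to converge are counted in
#' `convergence_failures` and excluded from all summaries.
#'
#' @param study Study number (1 linear, 2 quadratic, 3 quadratic with the
#'   intercept--quadratic covariance incorrectly fixed to zero in the
#'   analysis model).
#' @param method One of `"FIML"`, `"MI-wEMB"`, `"MI-wFCS"`, `"MI-llMLM"`,
#'   `"MI-lqMLM"`. Study 1 admits all five; Studies 2--3 exclude
#'   `"MI-llMLM"`.
#' @param n Sample size per replication.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param proportion Missing-proportion schedule, `"small"` or `"large"`.
#' @param replications Number of Monte Carlo replications.
#' @param m Number of imputations (MI methods only).
#' @param pooling Subset of `c("D2", "D3", "D4")` to compute.
#' @param sampler List with `iterations` and `burn_in` for the MCMC-based
#'   imputation methods (FCS and multilevel).
#' @param seed Master seed for this condition; per-replication seeds are
#'   derived with [derive_seed()].
#' @param se Compute standard errors and intervals (needed for coverage);
#'   disable for test-statistic-only runs.
#' @param alpha Significance level for rejection rates.
#' @param residual_var Population residual variance override, see
#'   [study_population()].
#' @param keep_records Also return the per-replication records.
#' @return A list of class `cell_summary`: condition descriptor,
#'   `parameters` (per-parameter truth, standardized bias, MSE, coverage),
#'   `tests` (rejection rate per pooling strategy), `replications_used`,
#'   `convergence_failures`, and optionally `records`.
#' @export
run_condition <- function(study, method, n, mechanism = "MCAR",
                          proportion = "small", replications = 100,
                          m = 100, pooling = c("D2", "D3", "D4"),
                          sampler = list(iterations = 2000, burn_in = 1000),
                          seed = 1, se = TRUE, alpha = 0.05,
                          residual_var = NULL, keep_records = FALSE) {
  method <- match.arg(method, ALL_METHODS)
  if (!(method %in% methods_for_study(study)))
    stop("method ", method, " is not part of Study ", study)
  pooling <- match.arg(pooling, c("D2", "D3", "D4"), several.ok = TRUE)
  pop <- study_population(study, residual_var = residual_var)
  aspec <- analysis_spec(study, time_codes = pop$spec$time_codes)
  k <- lrt_df(aspec)
  truth <- true_param_vector(pop$params, aspec, growth_only = TRUE)
  mspec <- calibrate_missingness(
    missingness_spec(mechanism, proportions = proportion),
    pop$params, pop$spec)

  cond_key <- paste(study, method, n, mechanism, proportion, sep = "|")
  records <- vector("list", replications)
  failures <- 0L
  for (r in seq_len(replications)) {
    set.seed(derive_seed(seed, cond_key, r))
    rec <- tryCatch(
      run_one_replication(pop, aspec, mspec, n, method, m, pooling,
                          sampler, k, se),
      error = function(e) list(status = conditionMessage(e)))
    if (is.null(rec$status)) rec$status <- "ok"
    if (rec$status != "ok") failures <- failures + 1L
    records[[r]] <- rec
  }

  ok <- vapply(records, function(x) x$status == "ok", logical(1))
  used <- records[ok]
  par_names <- names(truth)
  parameters <- NULL
  tests <- NULL
  if (length(used) >= 2) {
    est <- do.call(rbind, lapply(used, `[[`, "estimates"))[, par_names,
                                                           drop = FALSE]
    parameters <- data.frame(
      parameter = par_names,
      truth = unname(truth),
      std_bias = vapply(par_names, function(p)
        as.numeric(standardized_bias(est[, p], truth[[p]])), numeric(1)),
      mse = vapply(par_names, function(p)
        mean_squared_error(est[, p], truth[[p]]), numeric(1)),
      cic = NA_real_, row.names = NULL)
    if (se) {
      lo <- do.call(rbind, lapply(used, `[[`, "lower"))[, par_names,
                                                        drop = FALSE]
      hi <- do.call(rbind, lapply(used, `[[`, "upper"))[, par_names,
                                                        drop = FALSE]
      parameters$cic <- vapply(par_names, function(p)
        as.numeric(ci_coverage(lo[, p], hi[, p], truth[[p]])), numeric(1))
    }
    strategies <- if (method == "FIML") "LRT" else pooling
    tests <- data.frame(
      pooling = strategies,
      rejection_rate = vapply(strategies, function(s)
        as.numeric(rejection_rate(
          vapply(used, function(x) x$p_values[[s]], numeric(1)), alpha)),
        numeric(1)),
      row.names = NULL)
  }
  out <- list(study = study, method = method, n = n, mechanism = mechanism,
              proportion = proportion, m = if (method == "FIML") NA else m,
              alpha = alpha, df = k,
              parameters = parameters, tests = tests,
              replications_used = sum(ok),
              convergence_failures = failures,
              replications_attempted = replications)
  if (keep_records) out$records <- records
  class(out) <- "cell_summary"
  out
}

run_one_replication <- function(pop, aspec, mspec, n, method, m, pooling,
                                sampler, k, se) {
  Yfull <- simulate_growth(n, pop$params, pop$spec)
  inc <- impose_missingness(Yfull, mspec)

  if (method == "FIML") {
    sat <- fit_saturated(inc)
    if (!sat$converged) stop("saturated EM did not converge")
    fit <- fit_growth(inc, aspec, se = se,
                      start = list(mean = sat$mean, cov = sat$cov))
    if (!fit$converged) stop("growth fit did not converge")
    if (se && !fit$information_ok) stop("non-PD information matrix")
    test <- likelihood_ratio_test(fit, sat, df = k)
    ci <- if (se) wald_intervals(fit) else NULL
    return(list(status = "ok", estimates = fit$estimates,
                lower = if (se) stats::setNames(ci$lower, ci$parameter),
                upper = if (se) stats::setNames(ci$upper, ci$parameter),
                p_values = list(LRT = test$p_value),
                statistic = test$statistic))
  }

  imp <- switch(method,
    "MI-wEMB" = impute_emb(inc, m = m),
    "MI-wFCS" = impute_fcs(inc, m = m, iterations = sampler$iterations,
                           burn_in = sampler$burn_in),
    "MI-llMLM" = impute_mlm(inc, time_codes = pop$spec$time_codes,
                            form = "linear", m = m,
                            iterations = sampler$iterations,
                            burn_in = sampler$burn_in),
    "MI-lqMLM" = impute_mlm(inc, time_codes = pop$spec$time_codes,
                            form = "quadratic", m = m,
                            iterations = sampler$iterations,
                            burn_in = sampler$burn_in))

  sats <- lapply(imp$datasets, fit_saturated)
  fits <- lapply(seq_along(imp$datasets), function(i)
    fit_growth(imp$datasets[[i]], aspec, se = se,
               start = list(mean = sats[[i]]$mean, cov = sats[[i]]$cov)))
  if (!all(vapply(fits, `[[`, logical(1), "converged")))
    stop("a per-imputation growth fit did not converge")
  T_i <- mapply(function(f, s) max(-2 * (f$loglik - s$loglik), 0),
                fits, sats)

  lower <- upper <- estimates <- NULL
  if (se) {
    if (!all(vapply(fits, `[[`, logical(1), "information_ok")))
      stop("non-PD information matrix in an imputation fit")
    est_mat <- do.call(rbind, lapply(fits, `[[`, "estimates"))
    var_mat <- do.call(rbind, lapply(fits, function(f) f$se^2))
    pooled <- pool_rubin(est_mat, var_mat,
                         df_complete = fits[[1]]$n_used - fits[[1]]$npar)
    estimates <- pooled$estimates
    lower <- stats::setNames(pooled$intervals$lower,
                             pooled$intervals$parameter)
    upper <- stats::setNames(pooled$intervals$upper,
                             pooled$intervals$parameter)
  } else {
    estimates <- colMeans(do.call(rbind, lapply(fits, `[[`, "estimates")))
  }

  p_values <- list()
  if ("D2" %in% pooling)
    p_values$D2 <- pool_d2(T_i, k)$p_value
  if ("D3" %in% pooling)
    p_values$D3 <- pool_d3(imp, aspec, fits, sats, k = k)$p_value
  if ("D4" %in% pooling)
    p_values$D4 <- pool_d4(imp, aspec, fits, sats, k = k)$p_value

  list(status = "ok", estimates = estimates, lower = lower, upper = upper,
       p_values = p_values, statistics = T_i)
}

#' @export
print.cell_summary <- function(x, ...) {
  cat(sprintf("Study %d | %s | N = %d | %s, %s missingness\n", x$study,
              x$method, x$n, x$mechanism, x$proportion))
  cat(sprintf("  %d/%d replications used (%d convergence failures)\n",
              x$replications_used, x$replications_attempted,
              x$convergence_failures))
  if (!is.null(x$parameters)) {
    cat("  parameters:\n")
    print(x$parameters, digits = 3)
  }
  if (!is.null(x$tests)) {
    cat("  rejection rates (alpha =", x$alpha, "):\n")
    print(x$tests, digits = 3)
  }
  invisible(x)
}

#' Run a fully crossed simulation study
#'
#' Iterates [run_condition()] over the cross of methods, sample sizes,
#' mechanisms and proportion schedules in a configuration, and returns one
#' tidy results table with a row per condition and parameter (bias, MSE,
#' coverage) plus a row per condition and pooling strategy (rejection
#' rates). Per-cell seeds are derived deterministically from the master
#' seed, so re-running the same configuration reproduces the table exactly.
#'
#' @param config A list (or path to a YAML file) with elements `study`,
#'   `methods`, `ns`, `mechanisms`, `proportions`, `replications`, `m`,
#'   `pooling`, `sampler` (`iterations`, `burn_in`), `seed`, and optional
#'   `se`, `alpha`, `residual_var`.
#' @param out_dir Optional directory; when given, the parameter and test
#'   tables are written as CSV together with a JSON manifest of the
#'   configuration.
#' @param verbose Print per-cell progress.
#' @return List with data frames `parameters` and `tests`, and the list of
#'   `cell_summary` objects.
#' @export
run_study <- function(config, out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(methods = methods_for_study(config$study),
                   ns = c(150, 300, 600),
                   mechanisms = c("MCAR", "MAR"),
                   proportions = c("small", "large"),
                   replications = 100, m = 20,
                   pooling = c("D2", "D3", "D4"),
                   sampler = list(iterations = 2000, burn_in = 1000),
                   seed = 1, se = TRUE, alpha = 0.05,
                   residual_var = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$study)) stop("config must name a `study`")

  grid <- expand.grid(method = config$methods, n = config$ns,
                      mechanism = config$mechanisms,
                      proportion = config$proportions,
                      stringsAsFactors = FALSE)
  cells <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (verbose)
      message(sprintf("cell %d/%d: %s N=%d %s/%s", i, nrow(grid),
                      g$method, g$n, g$mechanism, g$proportion))
    cells[[i]] <- run_condition(
      study = config$study, method = g$method, n = g$n,
      mechanism = g$mechanism, proportion = g$proportion,
      replications = config$replications, m = config$m,
      pooling = config$pooling, sampler = config$sampler,
      seed = derive_seed(config$seed, config$study, g$method, g$n,
                         g$mechanism, g$proportion),
      se = config$se, alpha = config$alpha,
      residual_var = config$residual_var)
  }

  cond_cols <- function(cell, extra) {
    cbind(data.frame(study = cell$study, method = cell$method, n = cell$n,
                     mechanism = cell$mechanism,
                     proportion = cell$proportion,
                     replications_used = cell$replications_used,
                     convergence_failures = cell$convergence_failures),
          extra)
  }
  parameters <- do.call(rbind, lapply(cells, function(cell)
    if (is.null(cell$parameters)) NULL
    else cond_cols(cell, cell$parameters)))
  tests <- do.call(rbind, lapply(cells, function(cell)
    if (is.null(cell$tests)) NULL else cond_cols(cell, cell$tests)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(parameters, file.path(out_dir, "parameters.csv"),
                     row.names = FALSE)
    utils::write.csv(tests, file.path(out_dir, "tests.csv"),
                     row.names = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  list(parameters = parameters, tests = tests, cells = cells)
}

#' Analyze one wide-format dataset with several missing-data techniques
#'
#' Single-dataset workflow mirroring an applied analysis: fit a growth
#' model to a (possibly incomplete) wide table by FIML, and/or impute with
#' the MI methods and pool estimates (Rubin's rules) and LRT statistics
#' (D2/D3/D4). Produces a report with one estimates column per method and
#' the model-fit statistics.
#'
#' @param data Wide numeric matrix, data frame, or path to a CSV with one
#'   column per occasion (empty fields as missing markers).
#' @param spec Analysis-model [growth_spec()].
#' @param methods Methods to apply (default all that are applicable).
#' @param pooling Pooling strategies for the MI LRTs.
#' @param m Number of imputations.
#' @param sampler MCMC settings for FCS / multilevel imputation.
#' @param seed Master seed.
#' @return A list of class `dataset_report`: `estimates` (long data frame
#'   with parameter, method, estimate, se) and `fit` (data frame with the
#'   FIML LRT and pooled statistics per method).
#' @export
analyze_dataset <- function(data, spec,
                            methods = c("FIML", "MI-wEMB", "MI-wFCS",
                                        "MI-lqMLM"),
                            pooling = c("D2", "D3", "D4"), m = 100,
                            sampler = list(iterations = 2000,
                                           burn_in = 1000),
                            seed = 1) {
  if (is.character(data)) data <- read_wide_csv(data)
  Y <- as_outcome_matrix(data)
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  k <- lrt_df(spec)
  estimates <- NULL
  fit_rows <- NULL

  for (method in methods) {
    set.seed(derive_seed(seed, "analyze", method))
    if (method == "FIML") {
      sat <- fit_saturated(Y)
      fit <- fit_growth(Y, spec, start = list(mean = sat$mean,
                                              cov = sat$cov))
      test <- likelihood_ratio_test(fit, sat, df = k)
      estimates <- rbind(estimates, data.frame(
        parameter = names(fit$estimates), method = method,
        estimate = unname(fit$estimates), se = unname(fit$se)))
      fit_rows <- rbind(fit_rows, data.frame(
        method = method, statistic = "chi2", value = test$statistic,
        df1 = k, df2 = NA_real_, p_value = test$p_value))
      next
    }
    imp <- switch(method,
      "MI-wEMB" = impute_emb(Y, m = m),
      "MI-wFCS" = impute_fcs(Y, m = m, iterations = sampler$iterations,
                             burn_in = sampler$burn_in),
      "MI-llMLM" = impute_mlm(Y, time_codes = spec$time_codes,
                              form = "linear", m = m,
                              iterations = sampler$iterations,
                              burn_in = sampler$burn_in),
      "MI-lqMLM" = impute_mlm(Y, time_codes = spec$time_codes,
                              form = "quadratic", m = m,
                              iterations = sampler$iterations,
                              burn_in = sampler$burn_in))
    sats <- lapply(imp$datasets, fit_saturated)
    fits <- lapply(seq_along(imp$datasets), function(i)
      fit_growth(imp$datasets[[i]], spec,
                 start = list(mean = sats[[i]]$mean,
                              cov = sats[[i]]$cov)))
    est_mat <- do.call(rbind, lapply(fits, `[[`, "estimates"))
    var_mat <- do.call(rbind, lapply(fits, function(f) f$se^2))
    pooled <- pool_rubin(est_mat, var_mat,
                         df_complete = nrow(Y) - fits[[1]]$npar)
    estimates <- rbind(estimates, data.frame(
      parameter = names(pooled$estimates), method = method,
      estimate = unname(pooled$estimates),
      se = sqrt(unname(pooled$total_var))))
    T_i <- mapply(function(f, s) max(-2 * (f$loglik - s$loglik), 0),
                  fits, sats)
    for (strat in pooling) {
      pt <- switch(strat,
                   D2 = pool_d2(T_i, k),
                   D3 = pool_d3(imp, spec, fits, sats, k = k),
                   D4 = pool_d4(imp, spec, fits, sats, k = k))
      fit_rows <- rbind(fit_rows, data.frame(
        method = method, statistic = strat, value = pt$statistic,
        df1 = k, df2 = pt$df2, p_value = pt$p_value))
    }
  }
  structure(list(estimates = estimates, fit = fit_rows, df = k),
            class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat("Growth-model analysis report (LRT df =", x$df, ")\n\nEstimates:\n")
  wide <- stats::reshape(x$estimates, direction = "wide",
                         idvar = "parameter", timevar = "method")
  print(wide, digits = 3, row.names = FALSE)
  cat("\nModel fit:\n")
  print(x$fit, digits = 4, row.names = FALSE)
  invisible(x)
}
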