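# Shared fixtures and independent oracles used across the test files.

# A small linear population on the Study 1 scale with five occasions: cheap
# to simulate and fit, while exercising the same code paths as the full
# seven-occasion designs.
toy_linear_pop <- function(resvar = 4) {
  spec <- growth_spec(1, 0:4)
  params <- growth_params(c(10, 2),
                          matrix(c(4, 0.5, 0.5, 1), 2, 2),
                          residual_vars = resvar, n_occasions = 5)
  list(spec = spec, params = params)
}

# Mask a fraction of cells completely at random, keeping column 1 intact.
mask_mcar <- function(Y, frac = 0.2) {
  idx <- which(matrix(TRUE, nrow(Y), ncol(Y)), arr.ind = TRUE)
  idx <- idx[idx[, 2] > 1, , drop = FALSE]
  del <- idx[stats::runif(nrow(idx)) < frac, , drop = FALSE]
  Y[del] <- NA_real_
  Y
}

# Brute-force observed-data log-likelihood: loops rows and evaluates each
# marginal normal density directly with solve()/det(), independently of the
# pattern-grouped implementation under test.
rowwise_loglik <- function(Y, mu, Sigma) {
  total <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    if (!length(o)) next
    d <- Y[i, o] - mu[o]
    So <- Sigma[o, o, drop = FALSE]
    total <- total - 0.5 * (length(o) * log(2 * pi) +
                              log(det(So)) +
                              drop(t(d) %*% solve(So) %*% d))
  }
  total
}
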