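# Shared fixtures built in code at test time.

# draw n rows from N(0, Sigma), deterministic per seed
draw_mvn <- function(n, Sigma, seed) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * ncol(Sigma)), n) %*% chol(Sigma)
  colnames(Z) <- colnames(Sigma)
  tibble::as_tibble(Z)
}

# 1-factor data with given loadings, factor variance, residual variances
factor_sigma <- function(loadings, psi, theta, names = paste0("x", seq_along(loadings))) {
  S <- tcrossprod(loadings) * psi + diag(theta, length(loadings))
  dimnames(S) <- list(names, names)
  S
}

# simple regression dataset y = b x + e
regression_data <- function(n, b, seed, sd_e = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  tibble::tibble(x = x, y = b * x + stats::rnorm(n, sd = sd_e))
}

# Calibrated-recovery assertion: with many free parameters, "every |z| < 3"
# rejects a correct estimator on a sizeable share of seeds, so check instead
# that (a) estimates show no systematic drift, (b) the number of parameters
# outside 3 SE does not exceed the 99.5% Poisson envelope of the chance rate
# (0.27% per parameter), and (c) nothing is wildly off.
expect_calibrated_recovery <- function(estimate, true_value, se, info = NULL) {
  z <- (estimate - true_value) / se
  expect_lt(abs(mean(z)), 0.25)
  allowed <- stats::qpois(0.995, length(z) * 0.0027)
  expect_lte(sum(abs(z) > 3), max(allowed, 1L))
  expect_lt(max(abs(z)), 5)
  invisible(z)
}

# canonical term set of a model, for round-trip comparisons
term_key_set <- function(m) {
  t <- condsem:::canonical_terms(m$terms)
  fx <- ifelse(is.na(t$fixed), "free", format(t$fixed, digits = 12))
  sort(paste(t$lhs, t$op, t$rhs, fx))
}
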