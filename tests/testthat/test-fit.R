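test_that("just-identified factor model matches the covariance-ratio closed form", {
  Sigma <- factor_sigma(c(1, 0.8, 1.2), 1, c(0.5, 0.4, 0.6))
  d <- draw_mvn(400, Sigma, 42)
  f <- sem_fit(d, sem_model("f =~ x1 + x2 + x3"))
  S <- cov(d)
  est <- tidy(f)
  lam2 <- est$estimate[est$op == "=~" & est$rhs == "x2"]
  lam3 <- est$estimate[est$op == "=~" & est$rhs == "x3"]
  psi <- est$estimate[est$op == "~~" & est$lhs == "f"]
  expect_equal(lam2, S["x2", "x3"] / S["x1", "x3"], tolerance = 1e-6)
  expect_equal(lam3, S["x2", "x3"] / S["x1", "x2"], tolerance = 1e-6)
  expect_equal(psi, S["x1", "x2"] * S["x1", "x3"] / S["x2", "x3"],
               tolerance = 1e-6)
  expect_equal(f$fml, 0, tolerance = 1e-8)
  expect_equal(f$df, 0L)
})

test_that("composite-to-outcome model reproduces least squares exactly", {
  set.seed(11)
  d <- tibble::tibble(x1 = rnorm(300), x2 = rnorm(300) + 0.4 * x1,
                      x3 = rnorm(300) - 0.2 * x2)
  d$y <- 0.3 * d$x1 - 0.5 * d$x2 + 0.15 * d$x3 + rnorm(300)
  f <- sem_fit(d, sem_model("C <~ x1 + x2 + x3\ny ~ C"), se = FALSE)
  eff <- condsem:::composite_total_effects(f$ptab)
  ls <- lm(y ~ x1 + x2 + x3, d)
  expect_equal(unname(eff[c("x1", "x2", "x3")]), unname(coef(ls)[-1]),
               tolerance = 1e-6)
  # R^2 equivalence: 1 - implied residual share of var(y)
  pt <- tidy(f)
  th_y <- pt$estimate[pt$op == "~~" & pt$lhs == "y"]
  v_y <- var(d$y) * (nrow(d) - 1) / (nrow(d) - 1)
  r2_sem <- 1 - th_y / cov(d)["y", "y"]
  expect_equal(r2_sem, summary(ls)$r.squared, tolerance = 1e-6)
})

test_that("a saturated model reproduces the sample covariance with chisq 0", {
  set.seed(5)
  d <- tibble::tibble(a = rnorm(100), b = rnorm(100) + 0.5 * a,
                      c = rnorm(100) - 0.3 * b)
  f <- sem_fit(d, sem_model("a ~~ b\na ~~ c\nb ~~ c"), se = FALSE)
  expect_equal(f$chisq, 0, tolerance = 1e-7)
  expect_equal(f$df, 0L)
  skel <- f$skels[[1]]
  ram <- condsem:::ram_matrices(skel, f$theta)
  Sigma <- implied_covariance(ram$A, ram$S, f$obs_idx)
  expect_equal(unname(Sigma), unname(f$moments[[1]]$cov), tolerance = 1e-6)
})

test_that("regression standard errors match the analytic least-squares form", {
  d <- regression_data(250, b = 0.7, seed = 9)
  f <- sem_fit(d, sem_model("y ~ x"))
  pt <- tidy(f)
  se_sem <- pt$se[pt$op == "~"]
  ls <- summary(lm(y ~ x, d))
  # ML uses N in the residual variance where OLS uses N - 2
  n <- nrow(d)
  se_ml <- ls$coefficients["x", "Std. Error"] * sqrt((n - 2) / (n - 1))
  expect_equal(se_sem, se_ml, tolerance = 1e-3)

  # doubling the dataset by duplication shrinks the se by about 1/sqrt(2)
  d2 <- dplyr::bind_rows(d, d)
  f2 <- sem_fit(d2, sem_model("y ~ x"))
  se2 <- tidy(f2)$se[tidy(f2)$op == "~"]
  expect_equal(se2 / se_sem, 1 / sqrt(2), tolerance = 0.01)

  # standard errors on a non-converged fit are refused
  fbad <- f
  fbad$converged <- FALSE
  expect_error(standard_errors(fbad), "converge")
})

test_that("standardized estimates equal correlations where they should", {
  d <- regression_data(500, b = -0.6, seed = 21)
  f <- sem_fit(d, sem_model("y ~ x"))
  pt <- tidy(f)
  expect_equal(pt$std_estimate[pt$op == "~"], cor(d$x, d$y), tolerance = 1e-6)

  # standardized variance of an exogenous latent is 1
  Sigma <- factor_sigma(c(1, 0.9, 1.1), 1, c(0.4, 0.4, 0.4))
  dd <- draw_mvn(300, Sigma, 3)
  fc <- sem_fit(dd, sem_model("f =~ x1 + x2 + x3"))
  ptc <- tidy(fc)
  expect_equal(ptc$std_estimate[ptc$op == "~~" & ptc$lhs == "f"], 1,
               tolerance = 1e-8)
})

test_that("standardized solution is invariant to rescaling observed variables", {
  Sigma <- factor_sigma(c(1, 0.9, 1.1), 1, c(0.4, 0.4, 0.4))
  d <- draw_mvn(400, Sigma, 13)
  m <- sem_model("f =~ x1 + x2 + x3")
  f1 <- sem_fit(d, m, se = FALSE)
  d2 <- d
  d2$x2 <- d2$x2 * 37
  d2$x3 <- d2$x3 / 5
  f2 <- sem_fit(d2, m, se = FALSE)
  expect_equal(tidy(f1)$std_estimate, tidy(f2)$std_estimate, tolerance = 1e-6)
})

test_that("multi-group fit with identical groups equals the pooled fit", {
  Sigma <- factor_sigma(c(1, 0.9, 1.1), 1, c(0.4, 0.4, 0.4))
  d <- draw_mvn(300, Sigma, 17)
  dg <- dplyr::bind_rows(dplyr::mutate(d, g = "one"),
                         dplyr::mutate(d, g = "two"))
  f_pool <- sem_fit(d, sem_model("f =~ x1 + x2 + x3"), se = FALSE)
  f_grp <- sem_fit(dg, sem_model("f =~ x1 + x2 + x3", groups = "g"), se = FALSE)
  pt <- tidy(f_grp)
  for (g in c("one", "two")) {
    expect_equal(pt$estimate[pt$group == g], tidy(f_pool)$estimate,
                 tolerance = 1e-5, info = g)
  }
  expect_equal(f_grp$ngroups, 2L)
})

test_that("group-equality constraints share parameters across groups", {
  tm <- condition_fixture("colour_grouped")
  d <- simulate_from(tm, c(adult = 400, subadult = 300), 19)
  m <- sem_model("colour =~ hue + chroma + luminance", groups = "age_class",
                 group_equal = "loadings")
  # the equality constraint is deliberately misspecified for these groups, so
  # a boundary (Heywood) warning is expected
  f <- suppressWarnings(sem_fit(d, m, se = FALSE))
  pt <- tidy(f)
  lam <- pt[pt$op == "=~" & pt$free, ]
  by_rhs <- split(lam$estimate, lam$rhs)
  for (v in names(by_rhs)) expect_equal(diff(range(by_rhs[[v]])), 0)
  # constrained model has more df than the free one
  f_free <- sem_fit(d, sem_model("colour =~ hue + chroma + luminance",
                                 groups = "age_class"), se = FALSE)
  expect_gt(f$df, f_free$df)
})

test_that("missing rows are listwise-deleted and counted", {
  Sigma <- factor_sigma(c(1, 0.9, 1.1), 1, c(0.4, 0.4, 0.4))
  d <- draw_mvn(200, Sigma, 23)
  d$x1[c(3, 10, 50)] <- NA
  f <- sem_fit(d, sem_model("f =~ x1 + x2 + x3"), se = FALSE)
  expect_equal(f$n_dropped, 3L)
  expect_equal(f$nobs, 197L)
})

test_that("the chi-square of a correct model is centred on its df", {
  # energy-structure model has df 3; average chisq over replicate fits
  tm <- condition_fixture("energy")
  chis <- vapply(1:150, function(i) {
    d <- simulate_from(tm, 300, 3000 + i)
    f <- suppressWarnings(sem_fit(d, tm$model, se = FALSE))
    if (f$converged) f$chisq else NA_real_
  }, numeric(1))
  chis <- chis[!is.na(chis)]
  expect_gt(length(chis), 140)
  df <- model_df(tm$model)
  # MC standard error of the mean of chisq_df is sqrt(2 df / n)
  expect_lt(abs(mean(chis) - df), 4 * sqrt(2 * df / length(chis)))
})

test_that("fitting from a covariance matrix matches fitting from data", {
  Sigma <- factor_sigma(c(1, 0.9, 1.1), 1, c(0.4, 0.4, 0.4))
  d <- draw_mvn(250, Sigma, 29)
  m <- sem_model("f =~ x1 + x2 + x3")
  f1 <- sem_fit(d, m, se = FALSE)
  f2 <- sem_fit(NULL, m, sample_cov = cov(d), sample_nobs = nrow(d), se = FALSE)
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-7)
})
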