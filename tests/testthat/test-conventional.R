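test_that("PCA variance shares follow the 2x2 correlation eigenvalues", {
  # eigenvalues of a 2-variable correlation matrix are 1 +/- r, so PC1
  # explains (1 + r) / 2; with r = 1 that is everything
  set.seed(83)
  x <- rnorm(500)
  d <- tibble::tibble(a = x, b = 2 * x + 3)
  p <- principal_components(d, c("a", "b"))
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-12)

  S <- matrix(c(1, 0.91, 0.91, 1), 2)
  d2 <- draw_mvn(2000, `dimnames<-`(S, list(c("a", "b"), c("a", "b"))), 83)
  p2 <- principal_components(d2, c("a", "b"))
  r_hat <- cor(d2$a, d2$b)
  expect_equal(p2$variance_explained[1], (1 + r_hat) / 2, tolerance = 1e-10)
  expect_equal(r_hat, 0.91, tolerance = 0.02)
})

test_that("PCA matches an independent eigen-solver up to sign", {
  Sigma <- factor_sigma(c(1, 0.8, 1.2), 1, c(0.5, 0.4, 0.6))
  d <- draw_mvn(400, Sigma, 89)
  p <- principal_components(d, colnames(d))
  ref <- prcomp(d, center = TRUE, scale. = TRUE)
  for (k in 1:3) {
    expect_equal(unname(abs(p$loadings[, k])), unname(abs(ref$rotation[, k])),
                 tolerance = 1e-8)
  }
  expect_equal(p$variance_explained,
               unname(ref$sdev^2 / sum(ref$sdev^2)), tolerance = 1e-8)
  # sign convention: the largest-magnitude loading of each component positive
  for (k in 1:3) expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
})

test_that("PCA scores are uncorrelated and variance shares sum to one", {
  set.seed(97)
  d <- tibble::as_tibble(matrix(rnorm(300 * 4), 300,
                                dimnames = list(NULL, paste0("v", 1:4))))
  p <- principal_components(d, paste0("v", 1:4))
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-12)
  cors <- cor(p$scores)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
})

test_that("constant columns are reported by name", {
  d <- tibble::tibble(a = rnorm(10), b = rep(2, 10))
  expect_error(principal_components(d, c("a", "b")), "b")
})

test_that("residual regression is orthogonal to its predictors", {
  set.seed(101)
  d <- tibble::tibble(t = rnorm(200), h = rnorm(200) + 0.5 * t,
                      w = rnorm(200))
  d$mass <- 1 + 0.4 * d$t + 0.3 * d$h + rnorm(200)
  out <- residual_regression(d, "mass", c("t", "h", "w"))
  r <- out$.resid
  expect_lt(abs(sum(r)), 1e-8)
  for (v in c("t", "h", "w")) expect_lt(abs(sum(r * d[[v]])), 1e-7)
  # coefficients behind the residuals match lm directly
  expect_equal(coef(attr(out, "resid_fit")), coef(lm(mass ~ t + h + w, d)))

  # an exactly linear response leaves zero residuals
  d$lin <- 2 * d$t - d$h
  expect_lt(max(abs(residual_regression(d, "lin", c("t", "h"))$.resid)), 1e-10)

  # rank deficiency is an error
  d$t2 <- d$t
  expect_error(residual_regression(d, "mass", c("t", "t2")), "rank deficient")
})

test_that("the stepwise index is internally consistent and deterministic", {
  tm <- condition_fixture("condition")
  d <- simulate_from(tm, 600, 103)
  s1 <- stepwise_condition_index(d)
  s2 <- stepwise_condition_index(d)
  expect_equal(s1$rows, s2$rows)
  expect_equal(s1$step2_coefficients, s2$step2_coefficients)

  # step 3 equals the step-2 linear predictor recomputed by hand
  co <- s1$step2_coefficients
  beta <- stats::setNames(co$estimate, co$term)
  X <- cbind(1, s1$rows$resid_mass,
             as.matrix(d[c("buffy_coat", "haematocrit", "cholesterol",
                           "uric_acid", "corticosterone")]))
  manual <- as.numeric(X %*% beta[c("(Intercept)", "resid_mass", "buffy_coat",
                                    "haematocrit", "cholesterol", "uric_acid",
                                    "corticosterone")])
  expect_equal(s1$rows$index, manual, tolerance = 1e-10)
})

test_that("stepwise slopes agree with the joint SEM when nothing confounds", {
  # condition variables uncorrelated with the sizes: the no-confounding limit
  m <- condition_model("condition_composite")
  vals <- c(
    "size_corrected_mass ~ tarsus" = 0.25,
    "size_corrected_mass ~ head" = 0.20,
    "size_corrected_mass ~ wing" = 0.15,
    "size_corrected_mass ~~ size_corrected_mass" = 0.60,
    "mass ~~ mass" = 1e-4,  # essentially no measurement error either
    "condition <~ buffy_coat" = 0.10, "condition <~ haematocrit" = 0.10,
    "condition <~ cholesterol" = 0.05, "condition <~ uric_acid" = 0.05,
    "condition <~ corticosterone" = -0.80,
    "condition ~ density" = -0.35,
    "survival ~ condition" = 0.45,
    "survival ~~ survival" = 0.60,
    condsem:::block_values(c("tarsus", "head", "wing",
                             "buffy_coat", "haematocrit", "cholesterol",
                             "uric_acid", "corticosterone", "density"),
                           var = 1, cov = 0),
    condsem:::block_values(c("tarsus", "head", "wing"), var = NA, cov = 0.5))
  tm <- sem_true_model(m, condsem:::collapse_values(vals))
  d <- simulate_from(tm, 20000, 107)
  s <- stepwise_condition_index(d)
  co <- stats::setNames(s$step2_coefficients$estimate,
                        s$step2_coefficients$term)
  truth <- condsem:::composite_total_effects(tm$ptab)
  for (v in c("buffy_coat", "haematocrit", "cholesterol", "uric_acid",
              "corticosterone")) {
    expect_lt(abs(co[[v]] - truth[[v]]), 0.035)
  }
  expect_lt(abs(co[["resid_mass"]] - truth[["size_corrected_mass"]]), 0.035)
})
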