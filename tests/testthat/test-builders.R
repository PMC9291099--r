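test_that("all model variants emit identified models with non-negative df", {
  variants <- c("energy_cfa", "bill_colour_cfa_multigroup",
                "size_corrected_mass_mimic", "condition_composite",
                "full_model", "full_model_with_bodysize", "quadratic_mass")
  for (v in variants) {
    m <- condition_model(v)
    expect_true(m$identified, info = v)
    ng <- if (v == "bill_colour_cfa_multigroup") 2L else 1L
    expect_gte(model_df(m, n_groups = ng), 0L)
    # builders round-trip through serialize/parse
    m2 <- apply_identification(sem_model(serialize_model(m), groups = m$groups))
    expect_equal(term_key_set(m), term_key_set(m2), info = v)
  }
})

test_that("the composite keeps density out of its definition", {
  m <- condition_model("condition_composite")
  causes <- m$terms$rhs[m$terms$op == "<~"]
  expect_length(causes, 6L)
  expect_false("density" %in% causes)
  # density acts on the condition index through a regression instead
  expect_true(any(m$terms$op == "~" & m$terms$lhs == "condition" &
                    m$terms$rhs == "density"))
  # and the cross-validation form drops it
  m_cv <- condition_model("condition_composite", include_density = FALSE)
  expect_false("density" %in% m_cv$variables$name)
})

test_that("the full model carries the haematocrit/cholesterol error covariance", {
  m <- condition_model("full_model")
  expect_true(any(m$terms$op == "~~" &
                    ((m$terms$lhs == "haematocrit_c" &
                        m$terms$rhs == "cholesterol_c") |
                       (m$terms$lhs == "cholesterol_c" &
                          m$terms$rhs == "haematocrit_c"))))
  # hue stands in for bill colour, with its documented confounders
  expect_true(any(m$terms$op == "~" & m$terms$lhs == "hue_c" &
                    m$terms$rhs == "bill_tip"))
  expect_true(any(m$terms$op == "~" & m$terms$lhs == "hue_c" &
                    m$terms$rhs == "sex"))
  # confounder edge set is configuration, not hard-coded
  m2 <- condition_model("full_model", confounder_edges = c(
    list(hue = "bill_tip"),
    stats::setNames(rep(list("sex"), 5),
                    c("buffy_coat", "haematocrit", "cholesterol", "uric_acid",
                      "corticosterone"))))
  expect_false(any(m2$terms$lhs == "buffy_c" & m2$terms$rhs == "age_class"))
})

test_that("the quadratic variant adds squared mass with correlated errors", {
  m <- condition_model("quadratic_mass")
  expect_true("mass_sq" %in% m$terms$rhs[m$terms$op == "<~"])
  expect_true(any(m$terms$op == "~~" &
                    ((m$terms$lhs == "mass" & m$terms$rhs == "mass_sq") |
                       (m$terms$lhs == "mass_sq" & m$terms$rhs == "mass"))))
})

test_that("energy_cfa refuses to drop its identifying size block", {
  expect_error(condition_model("energy_cfa", include_sizes = FALSE),
               "under-identified")
})

test_that("role mapping rewrites dataset column names", {
  m <- condition_model("energy_cfa",
                       map = c(mass = "wgt", ratio = "bmi", tarsus = "tar",
                               head = "hd", wing = "wg"))
  expect_true(all(c("wgt", "bmi", "tar", "hd", "wg") %in% m$variables$name))
  expect_false("mass" %in% m$variables$name)
  expect_error(condition_model("energy_cfa", map = c(nonsense = "x")),
               "unknown role")
})

test_that("a true quadratic coefficient of zero is recovered as zero", {
  # simulate from the linear condition fixture, then add the squared-mass
  # column; the quadratic model's extra weight must be consistent with 0
  tm <- condition_fixture("condition")
  d <- simulate_from(tm, 4000, 73)
  d$mass_sq <- (d$mass - mean(d$mass))^2
  f <- suppressWarnings(sem_fit(d, condition_model("quadratic_mass")))
  expect_true(f$converged)
  pt <- tidy(f)
  w_sq <- pt[pt$op == "<~" & pt$rhs == "mass_sq", ]
  b <- pt$estimate[pt$op == "~" & pt$lhs == "survival" & pt$rhs == "condition"]
  # total effect of squared mass on survival, with a delta-method-free bound:
  # |w * b| should be within ~3 SE of zero (SE of the weight scaled by |b|)
  expect_lt(abs(w_sq$estimate * b), 3 * abs(b) * w_sq$se + 1e-8)
})

test_that("full model fitted to its own simulation recovers the truth", {
  tm <- condition_fixture("full")
  d <- simulate_from(tm, 10000, 79)
  f <- sem_fit(d, tm$model)
  expect_true(f$converged)
  j <- dplyr::inner_join(
    dplyr::filter(tidy(f), free),
    dplyr::filter(tidy(tm), free)[c("lhs", "op", "rhs", "true_value")],
    by = c("lhs", "op", "rhs"))
  expect_calibrated_recovery(j$estimate, j$true_value, j$se)
})
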